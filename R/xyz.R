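# Extended-XYZ snapshots: species tag, position (nm) and charge per row,
# box edge on the comment (lattice) line. Element tags: NP (core), AH
# (protonated site), A (ionized site), Na, Cl, H, OH.

.snapshot_tag <- function(species, charge) {
  name <- .species_name(species)
  ifelse(name == "core", "NP",
         ifelse(name == "site", ifelse(charge == 0, "AH", "A"), name))
}

.tag_species <- function(tag) {
  unname(c(NP = .SPECIES[["core"]], AH = .SPECIES[["site"]],
           A = .SPECIES[["site"]], Na = .SPECIES[["Na"]],
           Cl = .SPECIES[["Cl"]], H = .SPECIES[["H"]],
           OH = .SPECIES[["OH"]])[tag])
}

#' Write an extended-XYZ snapshot
#'
#' @param state a `pt_system` or a `pt_snapshot`.
#' @param path output file.
#' @export
write_snapshot <- function(state, path) {
  if (inherits(state, "pt_system")) {
    snap <- structure(list(species = core_species(state$core),
                           charge = core_charges(state$core),
                           pos = core_positions(state$core),
                           edge_length = state$box$edge_length),
                      class = "pt_snapshot")
  } else {
    stopifnot(inherits(state, "pt_snapshot"))
    snap <- state
  }
  n <- length(snap$species)
  header <- sprintf(paste0('Lattice="%.9f 0.0 0.0 0.0 %.9f 0.0 0.0 0.0 %.9f" ',
                           'Properties=species:S:1:pos:R:3:charge:R:1'),
                    snap$edge_length, snap$edge_length, snap$edge_length)
  rows <- if (n > 0) sprintf("%s %.9f %.9f %.9f %.9f",
                             .snapshot_tag(snap$species, snap$charge),
                             snap$pos[, 1], snap$pos[, 2], snap$pos[, 3],
                             snap$charge)
          else character(0)
  writeLines(c(as.character(n), header, rows), path)
  invisible(path)
}

#' Read an extended-XYZ snapshot
#'
#' @param path file written by [write_snapshot()].
#' @return A `pt_snapshot`: list with `species` (codes), `charge`, `pos`
#'   (n x 3, nm) and `edge_length`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("parse error at line 1: truncated XYZ file",
                              call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("parse error at line 1: expected atom count",
                     call. = FALSE)
  m <- regmatches(lines[2], regexec('Lattice="([^"]+)"', lines[2]))[[1]]
  if (length(m) < 2) stop("parse error at line 2: missing Lattice", call. = FALSE)
  lat <- as.numeric(strsplit(trimws(m[2]), "[[:space:]]+")[[1]])
  if (length(lat) != 9 || any(is.na(lat)))
    stop("parse error at line 2: malformed lattice", call. = FALSE)
  edge <- lat[1]
  if (length(lines) < 2 + n)
    stop(sprintf("parse error at line %d: expected %d atom rows",
                 length(lines) + 1L, n), call. = FALSE)
  species <- integer(n); charge <- numeric(n); pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[2 + i]), "[[:space:]]+")[[1]]
    if (length(f) != 5)
      stop(sprintf("parse error at line %d: expected 5 fields", 2 + i),
           call. = FALSE)
    sp <- .tag_species(f[1])
    if (is.na(sp))
      stop(sprintf("parse error at line %d: unknown species tag '%s'",
                   2 + i, f[1]), call. = FALSE)
    species[i] <- sp
    pos[i, ] <- as.numeric(f[2:4])
    charge[i] <- as.numeric(f[5])
    if (any(is.na(pos[i, ])) || is.na(charge[i]))
      stop(sprintf("parse error at line %d: non-numeric field", 2 + i),
           call. = FALSE)
  }
  structure(list(species = species, charge = charge, pos = pos,
                 edge_length = edge), class = "pt_snapshot")
}

#' @export
print.pt_snapshot <- function(x, ...) {
  cat(sprintf("<pt_snapshot> %d particles, box edge %.4f nm, net charge %g\n",
              length(x$species), x$edge_length, sum(x$charge)))
  invisible(x)
}
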