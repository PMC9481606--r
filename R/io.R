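# Interchange formats.
# CV time series travel as PLUMED-COLVAR-style whitespace tables (leading
# "#! FIELDS time ..." header, scientific notation with 9 significant
# digits so write -> read round-trips exactly at printed precision).
# Trajectories are XYZ; structures are a minimal PDB subset read through
# bio3d.

#' Read a COLVAR-style whitespace table
#'
#' Requires a leading `#! FIELDS` header; tolerates comment lines and
#' interleaved restart headers (their field sets must match), and checks
#' that time is strictly increasing after concatenation.
#'
#' @param path file path
#' @return data frame of numeric columns, class `colvar_series` when a
#'   `time` column is present
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1]], "#! FIELDS")) {
    stop("missing '#! FIELDS' header in ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[[1]])),
                     "\\s+")[[1]]
  ncolv <- length(fields)
  rows <- list()
  for (i in seq_along(lines)[-1]) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "#! FIELDS")) {
        f2 <- strsplit(trimws(sub("^#! FIELDS", "", ln)), "\\s+")[[1]]
        if (!identical(f2, fields)) {
          stop("restart header at line ", i,
               " declares different fields", call. = FALSE)
        }
      }
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(vals) != ncolv) {
      stop("ragged row at line ", i, ": expected ", ncolv, " values, got ",
           length(vals), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("no data rows in ", path, call. = FALSE)
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- fields
  if ("time" %in% fields) {
    if (any(diff(df$time) <= 0)) {
      stop("time is not strictly increasing after concatenation",
           call. = FALSE)
    }
    class(df) <- c("colvar_series", "data.frame")
  }
  df
}

#' Write a COLVAR-style whitespace table
#'
#' @param series data frame of numeric columns (a `colvar_series` or any
#'   table); column order is preserved
#' @param path file path
#' @param columns optional subset/order of columns to write
#' @export
write_colvar <- function(series, path, columns = NULL) {
  df <- as.data.frame(series)
  if (!is.null(columns)) df <- df[, columns, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  M <- as.matrix(df)
  body <- apply(M, 1L, function(r) paste(sprintf("%.8e", r),
                                         collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Read / write XYZ trajectories
#'
#' Multi-frame XYZ: per frame an atom count line, a comment line, then
#' `name x y z` rows.  All frames must have the same atom count.
#'
#' @param path file path
#' @return `read_xyz`: list with `frames` (list of `n x 3` matrices),
#'   `names` (atom names) and `comments`
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list(); comments <- character(0); nm <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[[i]]) == "") { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[[i]])))
    if (is.na(nat) || nat <= 0L) {
      stop("malformed atom count at line ", i, call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop("truncated frame starting at line ", i, call. = FALSE)
    }
    comments <- c(comments, lines[[i + 1L]])
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad)) {
      stop("malformed atom record at line ", i + 1L + bad[1],
           call. = FALSE)
    }
    nm_f <- vapply(parts, `[`, character(1), 1L)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(nm)) nm <- nm_f
    if (length(nm_f) != length(nm)) {
      stop("inconsistent atom count across frames", call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- co
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("no frames in ", path, call. = FALSE)
  list(frames = frames, names = nm, comments = comments)
}

#' @rdname read_xyz
#' @param frames list of `n x 3` coordinate matrices
#' @param names atom names (recycled)
#' @param comment per-frame comment (recycled)
#' @export
write_xyz <- function(frames, path, names = "O", comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(frames[[1]])
  nm <- rep_len(names, n)
  cm <- rep_len(comment, length(frames))
  for (f in seq_along(frames)) {
    writeLines(as.character(n), con)
    writeLines(cm[[f]], con)
    fr <- frames[[f]]
    writeLines(sprintf("%s %.6f %.6f %.6f", nm, fr[, 1], fr[, 2],
                       fr[, 3]), con)
  }
  invisible(path)
}

#' Read a (minimal) PDB structure into an atom table
#'
#' Wraps `bio3d::read.pdb`; exposes the ATOM/HETATM records as a data
#' frame for selection (e.g. alpha-carbons via `elety == "CA"`).
#'
#' @param path PDB file
#' @return data frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`, `type`
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
             chain = at$chain, resno = at$resno,
             x = at$x, y = at$y, z = at$z, type = at$type,
             stringsAsFactors = FALSE)
}

#' Select alpha-carbon coordinates from an atom table
#'
#' @param atoms a [read_structure()] table
#' @param resno optional residue-number filter
#' @param chain optional chain filter
#' @return `n x 3` coordinate matrix
#' @export
select_ca <- function(atoms, resno = NULL, chain = NULL) {
  keep <- atoms$elety == "CA"
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  as.matrix(atoms[keep, c("x", "y", "z")])
}

#' Write anchor points as CA records of a minimal PDB
#'
#' @param points `n x 3` coordinate matrix
#' @param path output file
#' @export
write_ca_pdb <- function(points, path) {
  P <- as.matrix(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(P)), seq_len(nrow(P)), P[, 1], P[, 2], P[, 3]), con)
  writeLines("END", con)
  invisible(path)
}

#' Read an XYZ or multi-model PDB trajectory as coordinate frames
#'
#' @param path trajectory file (`.xyz` or `.pdb`)
#' @param n_atoms optional expected atom count (e.g. from an accompanying
#'   topology); a mismatch is an error
#' @return list of `n x 3` coordinate matrices
#' @export
read_traj <- function(path, n_atoms = NULL) {
  frames <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    read_xyz(path)$frames
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    })
  }
  if (!is.null(n_atoms) && nrow(frames[[1]]) != n_atoms) {
    stop("trajectory has ", nrow(frames[[1]]), " atoms but the topology ",
         "declares ", n_atoms, call. = FALSE)
  }
  frames
}
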