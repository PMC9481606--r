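# Free-energy surfaces by reweighting.  Frames of a biased run are weighted
# by exp(beta V) (the constant part of the bias cancels in the normalised
# weights), histogrammed on a CV grid, and converted to
# F = -(1/beta) log P, min-zeroed, with a block-average standard error.

#' Reweighted free-energy surface from a biased CV series
#'
#' @param series a `colvar_series` containing the CV column and a bias column
#' @param cv_col name of the CV column (default: first CV of the series'
#'   CV map, or `"s"`)
#' @param bias_col name of the bias column
#' @param beta inverse temperature (default from the series attributes)
#' @param grid numeric vector of bin edges, or `NULL` to span the sampled
#'   range with `bins` bins
#' @param bins number of bins when `grid` is `NULL`
#' @param n_blocks number of blocks for the error estimate (`>= 2`)
#' @param discard fraction of initial frames discarded as equilibration
#' @param kind `"histogram"` (default) or `"kde"` (Gaussian kernel density
#'   with bandwidth `bw`)
#' @param bw KDE bandwidth (defaults to one bin width)
#' @return object of class `fes_grid`: a data frame with the bin centres,
#'   `free_energy` (min-zeroed) and `error` columns; attributes carry beta
#'   and the block count
#' @export
reweighted_fes <- function(series, cv_col = NULL, bias_col = "opes.bias",
                           beta = NULL, grid = NULL, bins = 100L,
                           n_blocks = 4L, discard = 0, kind = c("histogram",
                                                                "kde"),
                           bw = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(series))
  if (n_blocks < 2L) stop("'n_blocks' must be >= 2", call. = FALSE)
  if (!bias_col %in% names(series)) {
    stop("series has no bias column '", bias_col, "'", call. = FALSE)
  }
  if (is.null(cv_col)) {
    cvmap <- attr(series, "cv_map")
    cv_col <- if (!is.null(cvmap)) rownames(cvmap)[1] else "s"
  }
  if (!cv_col %in% names(series)) {
    stop("series has no CV column '", cv_col, "'", call. = FALSE)
  }
  beta <- beta %||% (1 / (attr(series, "kT") %||% 1))
  s <- series[[cv_col]]
  v <- series[[bias_col]]
  n <- length(s)
  if (discard > 0) {
    keep <- seq.int(floor(discard * n) + 1L, n)
    s <- s[keep]; v <- v[keep]; n <- length(s)
  }
  if (n < n_blocks) stop("empty blocks: fewer frames than blocks",
                         call. = FALSE)
  if (is.null(grid)) {
    rng <- range(s)
    grid <- seq(rng[1], rng[2], length.out = bins + 1L)
  }
  centers <- (grid[-1] + grid[-length(grid)]) / 2
  # log-sum-exp guarded weights
  w <- exp(beta * (v - max(v)))
  block_id <- ceiling(seq_len(n) / (n / n_blocks))
  dens_of <- function(idx) {
    if (kind == "histogram") {
      bin <- findInterval(s[idx], grid, rightmost.closed = TRUE,
                          all.inside = TRUE)
      as.vector(tapply(w[idx], factor(bin, levels = seq_along(centers)),
                       sum, default = 0))
    } else {
      bwv <- bw %||% diff(grid[1:2])
      ss <- s[idx]; ww <- w[idx]
      vapply(centers, function(c0) {
        sum(ww * exp(-0.5 * ((ss - c0) / bwv)^2))
      }, numeric(1))
    }
  }
  P_all <- dens_of(seq_len(n))
  P_all <- P_all / sum(P_all)
  F_all <- -log(P_all) / beta
  F_all <- F_all - min(F_all, na.rm = TRUE)
  F_blocks <- matrix(NA_real_, length(centers), n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_id == b)
    if (length(idx) == 0L) stop("empty blocks", call. = FALSE)
    Pb <- dens_of(idx)
    Pb <- Pb / sum(Pb)
    Fb <- -log(Pb) / beta
    F_blocks[, b] <- Fb - min(Fb[is.finite(Fb)])
  }
  err <- apply(F_blocks, 1L, function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 2L) return(NA_real_)
    sd(r) / sqrt(length(r))
  })
  out <- data.frame(centers, free_energy = F_all, error = err)
  names(out)[1] <- cv_col
  attr(out, "beta") <- beta
  attr(out, "n_blocks") <- n_blocks
  attr(out, "edges") <- grid
  class(out) <- c("fes_grid", "data.frame")
  out
}

#' Write / read a free-energy surface as a whitespace table
#'
#' Plain-text layout: a `#! FIELDS` header naming the columns, then one row
#' per grid node with 9 significant digits.
#'
#' @param fes an `fes_grid` data frame
#' @param path file path
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(fes), collapse = " ")), con)
  apply_fmt <- function(row) paste(sprintf("%.8e", as.numeric(row)),
                                   collapse = " ")
  writeLines(vapply(seq_len(nrow(fes)), function(i) apply_fmt(fes[i, ]),
                    character(1)), con)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  df <- read_colvar(path)
  class(df) <- c("fes_grid", "data.frame")
  df
}
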