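# Habitat use vs availability: compositional analysis (log-ratio Wilks
# lambda test with a pairwise ranking matrix) and Ivlev's electivity index.

#' Habitat use proportions from fixes
#'
#' @param fixes fixes as in [compute_mcp()].
#' @param raster a [habitat_raster()].
#' @return Named vector of proportions of fixes per class (sums to 1).
#' @export
habitat_use <- function(fixes, raster) {
  xy <- as_xy(fixes)
  cls <- raster_class_at(raster, xy[, 1], xy[, 2])
  if (anyNA(cls))
    stop("fix #", which(is.na(cls))[1], " lies outside the raster extent")
  counts <- tabulate(cls, nbins = length(raster$classes))
  stats::setNames(counts / sum(counts), raster$classes)
}

#' Habitat availability proportions within a home range
#'
#' Class-area shares of the raster cells whose centers fall inside the
#' home-range geometry (a convex polygon, an FK grid mask result, or a
#' `home_range_result` of either kind).
#'
#' @param geometry a `home_range_result`, or a counter-clockwise polygon
#'   matrix.
#' @param raster a [habitat_raster()].
#' @return Named vector of availability proportions (sums to 1).
#' @export
habitat_availability <- function(geometry, raster) {
  ny <- nrow(raster$values); nx <- ncol(raster$values)
  xc <- raster$xmin + (seq_len(nx) - 0.5) * raster$cell
  yc <- raster$ymin + (seq_len(ny) - 0.5) * raster$cell
  XX <- rep(xc, each = ny); YY <- rep(yc, times = nx)
  if (inherits(geometry, "home_range_result") &&
      geometry$estimator == "FK") {
    ud <- geometry$ud
    inside_ud <- which(geometry$mask)
    # map UD cells inside the isopleth to raster cells via their centers
    iy <- (inside_ud - 1) %% nrow(geometry$mask) + 1
    ix <- (inside_ud - 1) %/% nrow(geometry$mask) + 1
    px <- ud$xmin + (ix - 0.5) * ud$cell
    py <- ud$ymin + (iy - 0.5) * ud$cell
    cls <- raster_class_at(raster, px, py)
    cls <- cls[!is.na(cls)]
    if (length(cls) == 0) stop("home range does not overlap the raster")
    counts <- tabulate(cls, nbins = length(raster$classes))
  } else {
    poly <- if (inherits(geometry, "home_range_result")) geometry$polygon
            else as.matrix(geometry)
    inside <- point_in_convex(XX, YY, poly)
    if (!any(inside)) stop("polygon does not overlap the raster")
    cls <- as.vector(raster$values)[inside]
    counts <- tabulate(cls, nbins = length(raster$classes))
  }
  stats::setNames(counts / sum(counts), raster$classes)
}

#' Assemble a use-availability sample
#'
#' @param animal_id label.
#' @param use,avail named proportion vectors over the same classes.
#' @return One-row data.frame with `use.` and `avail.` prefixed columns.
#' @export
use_avail_sample <- function(animal_id, use, avail) {
  stopifnot(abs(sum(use) - 1) < 1e-9, abs(sum(avail) - 1) < 1e-9,
            identical(names(use), names(avail)))
  out <- data.frame(animal_id = animal_id, stringsAsFactors = FALSE)
  for (k in names(use)) out[[paste0("use.", k)]] <- unname(use[k])
  for (k in names(avail)) out[[paste0("avail.", k)]] <- unname(avail[k])
  out
}

#' Compositional analysis of habitat selection
#'
#' Per animal, the difference of log-ratios
#' `d_i = ln(u_i / u_ref) - ln(a_i / a_ref)` is formed for every non-reference
#' class. Wilks' lambda for the hypothesis that the mean difference vector is
#' zero is the determinant ratio of the centered to the raw cross-product
#' matrix; the test statistic is `-N ln(lambda)` on `D - 1` degrees of
#' freedom. The preference ranking comes from the pairwise matrix of mean
#' log-ratio differences with per-pair t statistics; classes are ordered by
#' their number of pairwise wins.
#'
#' @param samples data.frame of [use_avail_sample()] rows (one per animal).
#' @param zero_sub proportion substituted for zero use values before the log
#'   transform (the availability must already be positive everywhere).
#' @param ref reference class for the log-ratio transform; the result is
#'   invariant to this choice.
#' @param n_perm if > 0, adds a permutation p-value from animal-wise sign
#'   flips of the difference vectors (useful for small N).
#' @return Object of class `compositional_result`: `lambda`, `chi_square`,
#'   `df`, `p`, `ranking` (class names, most preferred first), `rank_matrix`
#'   (pairwise mean differences), `t_matrix`, `n_animals`, and optionally
#'   `p_perm`. When the cross-product matrix is singular (too few animals for
#'   the number of classes) the test fields are NA and only the ranking is
#'   returned, with a warning.
#' @export
compositional_analysis <- function(samples, zero_sub = 0.01, ref = "Water",
                                   n_perm = 0) {
  use_cols <- grep("^use\\.", names(samples), value = TRUE)
  classes <- sub("^use\\.", "", use_cols)
  D <- length(classes)
  N <- nrow(samples)
  if (N < 2) stop("need at least 2 animals")
  if (D < 2) stop("need at least 2 habitat classes")
  if (!ref %in% classes) stop("reference class '", ref, "' not among: ",
                              paste(classes, collapse = ", "))
  U <- as.matrix(samples[, paste0("use.", classes)])
  A <- as.matrix(samples[, paste0("avail.", classes)])
  if (any(A <= 0)) stop("availability must be positive for every class")
  U[U == 0] <- zero_sub
  U <- U / rowSums(U)

  logratio_diff <- function(i, j) log(U[, i] / U[, j]) - log(A[, i] / A[, j])

  # difference vectors relative to the reference class
  others <- setdiff(seq_len(D), match(ref, classes))
  dmat <- sapply(others, function(i) logratio_diff(i, match(ref, classes)))
  dmat <- matrix(dmat, nrow = N)

  raw <- crossprod(dmat)                       # SSCP about zero
  ctr <- crossprod(scale(dmat, scale = FALSE)) # centered SSCP
  lambda <- chi <- p <- NA_real_
  singular <- FALSE
  det_raw <- det(raw)
  if (max(abs(dmat)) < 1e-12) {
    # use identical to availability for every animal: no deviation at all
    lambda <- 1; chi <- 0; p <- 1
  } else if (!is.finite(det_raw) || det_raw <= .Machine$double.eps^2 ||
      N - 1 < D - 1) {
    singular <- TRUE
    warning("singular cross-product matrix (too few animals for ", D,
            " classes); returning ranking only")
  } else {
    lambda <- det(ctr) / det_raw
    lambda <- min(max(lambda, .Machine$double.xmin), 1)
    chi <- -N * log(lambda)
    p <- stats::pchisq(chi, df = D - 1, lower.tail = FALSE)
  }

  # pairwise ranking matrix
  rank_mat <- matrix(0, D, D, dimnames = list(classes, classes))
  t_mat <- matrix(NA_real_, D, D, dimnames = list(classes, classes))
  for (i in seq_len(D)) for (j in seq_len(D)) {
    if (i == j) next
    dd <- logratio_diff(i, j)
    rank_mat[i, j] <- mean(dd)
    sdd <- stats::sd(dd)
    t_mat[i, j] <- if (sdd > 0) mean(dd) / (sdd / sqrt(N)) else
      sign(mean(dd)) * Inf
  }
  wins <- rowSums(rank_mat > 0)
  ranking <- classes[order(wins, rowSums(rank_mat), decreasing = TRUE)]

  p_perm <- NULL
  if (n_perm > 0 && !singular) {
    stat_of <- function(dm) {
      r <- crossprod(dm); c2 <- crossprod(scale(dm, scale = FALSE))
      dr <- det(r)
      if (dr <= 0) return(NA_real_)
      -N * log(min(max(det(c2) / dr, .Machine$double.xmin), 1))
    }
    obs <- chi
    cnt <- 0L; tot <- 0L
    for (b in seq_len(n_perm)) {
      flip <- sample(c(-1, 1), N, replace = TRUE)
      s <- stat_of(dmat * flip)
      if (!is.na(s)) { tot <- tot + 1L; if (s >= obs) cnt <- cnt + 1L }
    }
    p_perm <- (cnt + 1) / (tot + 1)
  }

  structure(list(lambda = lambda, chi_square = chi, df = D - 1, p = p,
                 ranking = ranking, rank_matrix = rank_mat, t_matrix = t_mat,
                 n_animals = N, singular = singular, p_perm = p_perm),
            class = "compositional_result")
}

#' @export
print.compositional_result <- function(x, ...) {
  cat(sprintf("compositional analysis (N = %d): lambda = %.4f, X2 = %.2f, df = %d, p = %.4g\n",
              x$n_animals, x$lambda, x$chi_square, x$df, x$p))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  cat("  preference: ", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Ivlev's electivity index
#'
#' `E_i = (u_i - a_i) / (u_i + a_i)`, in [-1, 1]; 0 means use proportional to
#' availability. Classes with `u_i + a_i = 0` are reported NA.
#'
#' @param use,avail named proportion vectors over the same classes.
#' @return Named vector of electivity values.
#' @export
ivlev_index <- function(use, avail) {
  stopifnot(identical(names(use), names(avail)))
  tot <- use + avail
  out <- ifelse(tot > 0, (use - avail) / tot, NA_real_)
  stats::setNames(out, names(use))
}

#' Ivlev electivity bar chart for several animals
#'
#' @param E matrix of electivity values, animals x classes.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_ivlev <- function(E, ...) {
  graphics::barplot(t(E), beside = TRUE, ylim = c(-1, 1),
                    legend.text = colnames(E),
                    ylab = "Ivlev electivity", ...)
  graphics::abline(h = 0)
  invisible(NULL)
}
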