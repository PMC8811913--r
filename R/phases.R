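#' Standardize a trait table for ordination
#'
#' Centres and scales each trait column to mean 0, variance 1. Constant
#' columns cannot be scaled and are dropped with a warning.
#'
#' @param trait_table data.frame with a `day` column and numeric trait
#'   columns, or a plain numeric matrix (rows = timepoints).
#' @return Numeric matrix of z-scores with timepoints as rows (rownames =
#'   days when available).
#' @export
standardize_traits <- function(trait_table) {
  if (is.data.frame(trait_table)) {
    days <- if ("day" %in% names(trait_table)) trait_table$day else NULL
    m <- as.matrix(trait_table[, setdiff(names(trait_table), "day"),
                               drop = FALSE])
    if (!is.null(days)) rownames(m) <- as.character(days)
  } else {
    m <- as.matrix(trait_table)
  }
  if (!is.numeric(m)) stop_input("trait values must be numeric")
  if (nrow(m) < 2 || ncol(m) < 1) {
    stop_input("need at least 2 timepoints and 1 trait")
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(m) == 0) stop_input("no non-constant traits left")
  scale(m, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Principal component analysis of a timepoint-by-variable matrix
#'
#' Eigen-decomposes the covariance matrix of the (typically standardized)
#' input, i.e. the correlation matrix when given z-scores. Component
#' orientation is made deterministic by flipping each loading vector so
#' that its largest-magnitude entry is positive.
#'
#' @param z Numeric matrix, rows = observations (timepoints), columns =
#'   variables. For the correlation form, pass the output of
#'   [standardize_traits()].
#' @return Object of class `"phase_pca"`: list with `scores` (observation
#'   x component), `loadings` (variable x component), `explained_variance`
#'   (fraction per component, non-increasing) and `sdev`.
#' @export
run_pca <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop_input("need at least 2 observations for PCA")
  z_c <- scale(z, center = TRUE, scale = FALSE)
  cv <- stats::cov(z_c)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  k <- min(nrow(z) - 1L, ncol(z))
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- z_c %*% vec
  dimnames(vec) <- list(colnames(z), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(z), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = vec,
                 explained_variance = ev[seq_len(k)] / sum(ev),
                 sdev = sqrt(ev[seq_len(k)])),
            class = "phase_pca")
}

#' @export
print.phase_pca <- function(x, ...) {
  ev <- round(100 * x$explained_variance, 1)
  cat("PCA:", nrow(x$scores), "timepoints,", nrow(x$loadings), "variables\n")
  cat("  variance explained (%):", paste(utils::head(ev, 5), collapse = ", "),
      if (length(ev) > 5) "..." else "", "\n")
  invisible(x)
}

#' Segment a time course into NRep / transition / NS phases
#'
#' Partitions the timepoints into two clusters on the first two principal
#' components using k-means initialized at the earliest and latest
#' timepoints' scores (deterministic), maps the clusters to NRep and NS by
#' time order, then relabels as `"transition"` any timepoint whose
#' distances to the two cluster centroids differ by less than the ratio
#' `tau` (i.e. far/near < tau): such points sit between the two
#' equilibrium states.
#'
#' @param model A [run_pca()] fit (or any list with a `scores` matrix).
#' @param time_axis Numeric day per timepoint, same order as the score
#'   rows.
#' @param tau Centroid-distance ratio below which a point is called
#'   transitional; must be > 1.
#' @return factor of labels in `c("NRep", "transition", "NS")` with
#'   attributes `"centroids"` and `"cluster"`.
#' @export
segment_phases <- function(model, time_axis, tau = 1.5) {
  if (tau <= 1) stop_input("`tau` must be > 1")
  sc <- model$scores[, seq_len(min(2L, ncol(model$scores))), drop = FALSE]
  n <- nrow(sc)
  if (n < 4) stop_input("need scores for at least 4 timepoints")
  if (length(time_axis) != n) {
    stop_input("`time_axis` length must match the score rows")
  }
  ord <- order(time_axis)
  lab <- rep("NRep", n)
  if (max(dist(sc)) < 1e-12) {
    warning("all timepoints identical; single cluster, labelled NRep",
            call. = FALSE)
  } else {
    centers <- sc[c(ord[1], ord[n]), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(sc, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    cl <- km$cluster
    # map clusters to phases by mean time
    mt <- tapply(time_axis, cl, mean)
    early <- as.integer(names(mt)[which.min(mt)])
    lab <- ifelse(cl == early, "NRep", "NS")
    d1 <- sqrt(rowSums((sc - matrix(km$centers[1, ], n, ncol(sc),
                                    byrow = TRUE))^2))
    d2 <- sqrt(rowSums((sc - matrix(km$centers[2, ], n, ncol(sc),
                                    byrow = TRUE))^2))
    d_near <- pmin(d1, d2)
    d_far <- pmax(d1, d2)
    lab[d_far < tau * pmax(d_near, .Machine$double.eps)] <- "transition"
    out <- factor(lab, levels = c("NRep", "transition", "NS"))
    attr(out, "centroids") <- km$centers
    attr(out, "cluster") <- cl
    return(out)
  }
  factor(lab, levels = c("NRep", "transition", "NS"))
}

#' Five-phase convention for expression averaging
#'
#' Collapses NRep and NS member days while detaching days 5, 6 and 15 as
#' singleton phases (`D5`, `D6`, `D15`), regardless of the cluster day 15
#' fell into: the late starved state diverges again at the transcriptomic
#' level. Phases whose day is absent from the axis are simply missing,
#' with a warning.
#'
#' @param labels Output of [segment_phases()] (or a character vector in
#'   `NRep`/`transition`/`NS`).
#' @param time_axis Numeric day per timepoint.
#' @return factor in `c("NRep", "D5", "D6", "NS", "D15")`.
#' @export
five_phase_labels <- function(labels, time_axis) {
  if (length(labels) != length(time_axis)) {
    stop_input("`labels` and `time_axis` lengths differ")
  }
  out <- as.character(labels)
  # transition days are normally 5-6 (singletons below); any others join
  # the temporally nearer equilibrium phase
  tr <- out == "transition"
  out[tr] <- ifelse(time_axis[tr] < 5.5, "NRep", "NS")
  out[time_axis == 5] <- "D5"
  out[time_axis == 6] <- "D6"
  out[time_axis == 15] <- "D15"
  absent <- setdiff(c(5, 6, 15), time_axis)
  if (length(absent)) {
    warning("day(s) ", paste(absent, collapse = ", "),
            " absent from the axis; their phases are missing", call. = FALSE)
  }
  factor(out, levels = c("NRep", "D5", "D6", "NS", "D15"))
}
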