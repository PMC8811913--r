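#' Construct an omics matrix
#'
#' Light container for feature-by-timepoint abundance or log2 fold-change
#' data: a numeric matrix with feature IDs as rownames and day labels
#' (`"D-2"` ... `"D15"`, `"D10/11"` for the pooled late metabolomics
#' sample) as colnames, plus attributes recording the timepoints, the data
#' kind and whether values are already log2FC.
#'
#' @param values Numeric matrix, features x timepoints.
#' @param timepoints Numeric days (strictly increasing), one per column.
#' @param kind `"transcript"` or `"metabolite"`.
#' @param log2fc Logical: are the values log2 fold changes (vs raw
#'   abundances)?
#' @param fdr Optional matrix of per-feature, per-timepoint adjusted
#'   p-values, same dimensions as `values`.
#' @param control_reference Free-text description of the control columns.
#' @return Matrix of class `"omics_matrix"`.
#' @export
omics_matrix <- function(values, timepoints, kind = c("transcript", "metabolite"),
                         log2fc = FALSE, fdr = NULL,
                         control_reference = "pre step-down timepoints") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_input("`values` must be numeric")
  if (length(timepoints) != ncol(values)) {
    stop_input("`timepoints` must have one entry per column")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop_input("`timepoints` must be strictly increasing")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0(if (kind == "transcript") "gene" else "cmp",
                               seq_len(nrow(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop_input("duplicate feature IDs: ",
               paste(unique(rownames(values)[duplicated(rownames(values))]),
                     collapse = ", "))
  }
  colnames(values) <- day_label(timepoints)
  if (!is.null(fdr)) {
    fdr <- as.matrix(fdr)
    if (!identical(dim(fdr), dim(values))) {
      stop_input("`fdr` dimensions must match `values`")
    }
    dimnames(fdr) <- dimnames(values)
  }
  structure(values, class = c("omics_matrix", "matrix", "array"),
            timepoints = as.numeric(timepoints), kind = kind,
            log2fc = log2fc, fdr = fdr, control_reference = control_reference)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d %s feature(s) x %d timepoint(s) [%s]%s\n",
              nrow(x), attr(x, "kind"), ncol(x),
              paste(colnames(x), collapse = " "),
              if (isTRUE(attr(x, "log2fc"))) ", log2FC" else ", abundance"))
  invisible(x)
}

om_timepoints <- function(m) attr(m, "timepoints")

#' Subset an omics matrix to a feature set
#'
#' Keeps the container attributes (timepoints, kind, log2FC flag, FDR)
#' intact, which plain `[` subsetting would drop.
#'
#' @param m An [omics_matrix()].
#' @param features Character IDs (or integer indices) of rows to keep.
#' @return An [omics_matrix()] restricted to `features`.
#' @export
subset_features <- function(m, features) {
  stopifnot(inherits(m, "omics_matrix"))
  vals <- unclass(m)[features, , drop = FALSE]
  fdr <- attr(m, "fdr")
  omics_matrix(vals, om_timepoints(m), kind = attr(m, "kind"),
               log2fc = attr(m, "log2fc"),
               fdr = if (!is.null(fdr)) fdr[features, , drop = FALSE],
               control_reference = attr(m, "control_reference"))
}

#' Log2 fold change against a control reference
#'
#' Computes `log2((x + pseudocount) / (mean(control) + pseudocount))` per
#' feature, where the control is the mean abundance over the control
#' columns (by default every pre-step-down timepoint, day < 0).
#'
#' @param m An abundance [omics_matrix()].
#' @param control_columns Indices or day labels of the control columns;
#'   default: all columns with negative days.
#' @param pseudocount Added to numerator and denominator; use 1 for
#'   count-like abundances, 0 for normalized intensities.
#' @return A log2FC [omics_matrix()] over the non-control timepoints, with
#'   any `fdr` attribute subset accordingly.
#' @export
compute_log2fc <- function(m, control_columns = NULL, pseudocount = 1) {
  stopifnot(inherits(m, "omics_matrix"))
  if (isTRUE(attr(m, "log2fc"))) {
    stop_input("matrix is already log2FC")
  }
  if (any(m < 0)) stop_input("abundances must be >= 0")
  check_number(pseudocount, "pseudocount", 0)
  tp <- om_timepoints(m)
  if (is.null(control_columns)) {
    control_columns <- which(tp < 0)
  } else if (is.character(control_columns)) {
    control_columns <- match(control_columns, colnames(m))
  }
  if (length(control_columns) == 0 || anyNA(control_columns)) {
    stop_input("no control columns identified")
  }
  ctrl <- rowMeans(m[, control_columns, drop = FALSE])
  keep <- setdiff(seq_len(ncol(m)), control_columns)
  lfc <- log2(sweep(m[, keep, drop = FALSE] + pseudocount, 1,
                    ctrl + pseudocount, "/"))
  fdr <- attr(m, "fdr")
  omics_matrix(lfc, tp[keep], kind = attr(m, "kind"), log2fc = TRUE,
               fdr = if (!is.null(fdr)) fdr[, keep, drop = FALSE],
               control_reference = paste("mean of",
                                         paste(colnames(m)[control_columns],
                                               collapse = ", ")))
}

#' Retention filter specification
#'
#' @param fdr_max Transcript FDR ceiling (default 0.001).
#' @param lfc_min_transcript Minimum |log2FC| for transcripts (default 1).
#' @param lfc_min_metabolite Minimum |log2FC| for metabolites (default 2).
#' @param min_timepoints Number of timepoints at which the thresholds must
#'   hold jointly (default 1).
#' @return list of class `"filter_spec"`.
#' @export
filter_spec <- function(fdr_max = 0.001, lfc_min_transcript = 1,
                        lfc_min_metabolite = 2, min_timepoints = 1) {
  check_number(fdr_max, "fdr_max", 0, strict_lower = TRUE)
  check_number(lfc_min_transcript, "lfc_min_transcript", 0, strict_lower = TRUE)
  check_number(lfc_min_metabolite, "lfc_min_metabolite", 0, strict_lower = TRUE)
  check_number(min_timepoints, "min_timepoints", 0, strict_lower = TRUE)
  structure(list(fdr_max = fdr_max, lfc_min_transcript = lfc_min_transcript,
                 lfc_min_metabolite = lfc_min_metabolite,
                 min_timepoints = min_timepoints), class = "filter_spec")
}

#' Differentially-expressed-gene retention filter
#'
#' A gene is retained when `FDR <= fdr_max` and `|log2FC| >=
#' lfc_min_transcript` hold at the same timepoint, for at least
#' `min_timepoints` timepoints (defaults: FDR <= 0.001, |log2FC| >= 1, one
#' timepoint).
#'
#' @param lfc A log2FC transcript [omics_matrix()] carrying an `fdr`
#'   attribute (or pass `fdr` separately).
#' @param fdr Optional FDR matrix overriding the attribute.
#' @param spec A [filter_spec()].
#' @return Character vector of retained feature IDs; attribute
#'   `"qualifying"` gives the per-feature count of qualifying timepoints.
#' @export
filter_transcripts <- function(lfc, fdr = attr(lfc, "fdr"),
                               spec = filter_spec()) {
  stopifnot(inherits(lfc, "omics_matrix"))
  if (!isTRUE(attr(lfc, "log2fc"))) {
    stop_input("`lfc` must be a log2FC matrix (run compute_log2fc first)")
  }
  if (is.null(fdr)) {
    stop_input("no FDR available: supply differential-test results or run ",
               "stand_in_de_test() on the replicated abundances")
  }
  fdr <- as.matrix(fdr)
  if (!identical(dim(fdr), dim(unclass(lfc)))) {
    stop_input("`fdr` dimensions must match the log2FC matrix")
  }
  ok <- (fdr <= spec$fdr_max) & (abs(lfc) >= spec$lfc_min_transcript)
  n_ok <- rowSums(ok)
  keep <- rownames(lfc)[n_ok >= spec$min_timepoints]
  structure(keep, qualifying = n_ok)
}

#' Responsive-metabolite retention filter
#'
#' Retains compounds whose |log2FC| reaches `lfc_min_metabolite` (default
#' 2) at one or more timepoints.
#'
#' @inheritParams filter_transcripts
#' @return Character vector of retained compound IDs.
#' @export
filter_metabolites <- function(lfc, spec = filter_spec()) {
  stopifnot(inherits(lfc, "omics_matrix"))
  if (!isTRUE(attr(lfc, "log2fc"))) {
    stop_input("`lfc` must be a log2FC matrix, not raw abundances")
  }
  n_ok <- rowSums(abs(lfc) >= spec$lfc_min_metabolite)
  rownames(lfc)[n_ok >= spec$min_timepoints]
}

#' Stand-in per-timepoint differential test
#'
#' Documented replacement for a full count-model differential-expression
#' analysis: a per-feature pooled-variance two-sample t-test of each
#' timepoint's replicates against the control group's replicates (exact at
#' the nominal level under equal group variances, which typical replicate
#' designs warrant), with Benjamini-Hochberg adjustment across features
#' within each timepoint. Degenerate zero-variance features are decided
#' exactly: equal group means give p = 1, different means p = 0.
#'
#' @param abundance Numeric matrix, features x samples (replicate
#'   columns).
#' @param groups Factor/vector assigning each column to a timepoint group.
#' @param control Level of `groups` acting as the control.
#' @return list with matrices `p` and `fdr` (features x non-control
#'   groups).
#' @export
stand_in_de_test <- function(abundance, groups, control) {
  abundance <- as.matrix(abundance)
  groups <- as.factor(groups)
  if (length(groups) != ncol(abundance)) {
    stop_input("`groups` must have one entry per column")
  }
  if (!control %in% levels(groups)) stop_input("`control` not in `groups`")
  if (any(table(groups) < 2)) {
    stop_input("every group needs at least 2 replicates")
  }
  ctrl_m <- abundance[, groups == control, drop = FALSE]
  lv <- setdiff(levels(groups), control)
  pooled_p <- function(a, b) {
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- numeric(nrow(a))
    deg <- se == 0
    p[deg] <- ifelse(m1[deg] == m2[deg], 1, 0)
    i <- !deg
    tt <- (m1[i] - m2[i]) / se[i]
    p[i] <- 2 * stats::pt(-abs(tt), n1 + n2 - 2)
    p
  }
  p <- vapply(lv, function(g) {
    pooled_p(abundance[, groups == g, drop = FALSE], ctrl_m)
  }, numeric(nrow(abundance)))
  rownames(p) <- rownames(abundance)
  fdr <- apply(p, 2, stats::p.adjust, method = "BH")
  list(p = p, fdr = fdr)
}

#' Exhaustive compound-gene unit-slope screen
#'
#' Regresses every retained compound's log2FC pattern on every retained
#' gene's log2FC pattern over their shared timepoints (ordinary least
#' squares) and retains the combinations showing a direct, significant,
#' unit-slope relation: `|slope|` within `slope_window` and the two-sided
#' slope t-test (df = n - 2) below `alpha`. Pairs with fewer than
#' `min_points` shared timepoints or a zero-variance gene pattern are
#' skipped with a reason code.
#'
#' The pooled metabolomics timepoint day "10/11" (encoded 10.5) is matched
#' against the mean of the transcript values at days 10 and 11; other
#' timepoints match exactly. Supply `timepoint_map` to override (a named
#' list: metabolite day -> transcript day(s), averaged when several).
#'
#' @param metab_lfc,gene_lfc log2FC [omics_matrix()] objects, already
#'   restricted to the retained compounds/genes.
#' @param timepoint_map Optional explicit mapping (named list, names =
#'   metabolite days as character).
#' @param slope_window Two-sided |slope| acceptance window, default
#'   `c(0.95, 1.05)`.
#' @param alpha Slope-test significance level, default 0.05.
#' @param min_points Minimum shared timepoints, default 3.
#' @param positive_only If `TRUE`, restrict to positive slopes in the
#'   window (strict "direct correlation" reading); default keeps both
#'   signs and records the sign via the slope itself.
#' @param adjust_p Optionally BH-adjust the screen p-values across all
#'   tested pairs before applying `alpha` (off by default; the retention
#'   rule applies no multiplicity correction).
#' @return data.frame of class `"pair_screen"`: one row per tested pair
#'   with `compound_id`, `gene_id`, `slope`, `intercept`, `p_value`,
#'   `n_points`, `retained`; skipped pairs appear with `NA` statistics and
#'   a `skip_reason`. Attribute `"retained_compounds"` lists the distinct
#'   compounds in retained pairs.
#' @export
pair_screen <- function(metab_lfc, gene_lfc, timepoint_map = NULL,
                        slope_window = c(0.95, 1.05), alpha = 0.05,
                        min_points = 3, positive_only = FALSE,
                        adjust_p = FALSE) {
  stopifnot(inherits(metab_lfc, "omics_matrix"),
            inherits(gene_lfc, "omics_matrix"))
  if (!isTRUE(attr(metab_lfc, "log2fc")) || !isTRUE(attr(gene_lfc, "log2fc"))) {
    stop_input("both inputs must be log2FC matrices")
  }
  mtp <- om_timepoints(metab_lfc)
  gtp <- om_timepoints(gene_lfc)
  if (is.null(timepoint_map)) {
    timepoint_map <- default_timepoint_map(mtp, gtp)
  }
  shared_m <- which(as.character(mtp) %in% names(timepoint_map))
  if (length(shared_m) < min_points) {
    stop_input("fewer than ", min_points, " shared timepoints after mapping")
  }
  C <- unclass(metab_lfc)[, shared_m, drop = FALSE]
  keys <- as.character(mtp[shared_m])
  tmp <- vapply(keys, function(key) {
    cols <- match(timepoint_map[[key]], gtp)
    rowMeans(unclass(gene_lfc)[, cols, drop = FALSE])
  }, numeric(nrow(gene_lfc)))
  if (!is.matrix(tmp)) tmp <- matrix(tmp, nrow = 1,
                                     dimnames = list(rownames(gene_lfc)))
  G <- t(tmp)  # shared timepoints x genes
  n <- nrow(G)
  Cc <- C - rowMeans(C)
  Gm <- colMeans(G)
  Gc <- sweep(G, 2, Gm)
  sxx <- colSums(Gc^2)
  zero_var <- sxx <= .Machine$double.eps * n
  sxy <- Cc %*% Gc                       # compounds x genes
  slope <- sweep(sxy, 2, ifelse(zero_var, NA, sxx), "/")
  intercept <- rowMeans(C) - sweep(slope, 2, Gm, "*")
  sse <- pmax(rowSums(Cc^2) - slope^2 * rep(sxx, each = nrow(C)), 0)
  df <- n - 2
  se <- sqrt(sweep(sse / df, 2, sxx, "/"))
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.nan(p)] <- 0   # exact fit: zero residual variance

  res <- data.frame(
    compound_id = rep(rownames(C), times = ncol(G)),
    gene_id = rep(colnames(sxy), each = nrow(C)),
    slope = as.vector(slope),
    intercept = as.vector(intercept),
    p_value = as.vector(p),
    n_points = n,
    stringsAsFactors = FALSE)
  res$skip_reason <- ifelse(rep(zero_var, each = nrow(C)),
                            "zero-variance gene pattern", NA_character_)
  p_eff <- if (adjust_p) stats::p.adjust(res$p_value, method = "BH") else res$p_value
  in_window <- if (positive_only) {
    res$slope >= slope_window[1] & res$slope <= slope_window[2]
  } else {
    abs(res$slope) >= slope_window[1] & abs(res$slope) <= slope_window[2]
  }
  res$retained <- !is.na(res$slope) & in_window & p_eff < alpha &
    res$n_points >= min_points
  structure(res, class = c("pair_screen", "data.frame"),
            retained_compounds = unique(res$compound_id[res$retained]),
            slope_window = slope_window, alpha = alpha)
}

# Default metabolite -> transcript timepoint mapping: exact day matches,
# plus the pooled day 10.5 ("10/11") matched to the mean of days 10 and 11
# when both exist.
default_timepoint_map <- function(mtp, gtp) {
  map <- list()
  for (d in mtp) {
    key <- as.character(d)
    if (d %in% gtp) {
      map[[key]] <- d
    } else if (isTRUE(all.equal(d, 10.5)) && all(c(10, 11) %in% gtp)) {
      map[[key]] <- c(10, 11)
    }
  }
  map
}

#' @export
print.pair_screen <- function(x, ...) {
  n_ret <- sum(x$retained, na.rm = TRUE)
  cat("Pair screen:", nrow(x), "compound-gene combinations tested\n")
  cat("  retained:", n_ret, "combinations involving",
      length(attr(x, "retained_compounds")), "distinct compounds\n")
  invisible(x)
}

#' Average an omics matrix into the five-phase convention
#'
#' Collapses NRep and NS member timepoints to their mean while passing the
#' singleton phases D5, D6 and D15 through, yielding one column per
#' present phase in the order NRep, D5, D6, NS, D15.
#'
#' @param m An [omics_matrix()].
#' @param phases factor from [five_phase_labels()], one label per column
#'   of `m`.
#' @return Numeric matrix, features x phases. Phases with no member day
#'   are omitted with a warning.
#' @export
phase_average <- function(m, phases) {
  stopifnot(inherits(m, "omics_matrix"))
  phases <- factor(phases, levels = c("NRep", "D5", "D6", "NS", "D15"))
  if (length(phases) != ncol(m)) {
    stop_input("`phases` must have one label per matrix column")
  }
  present <- levels(phases)[levels(phases) %in% phases]
  if (length(present) < 5) {
    warning("phase(s) with no member day omitted: ",
            paste(setdiff(levels(phases), present), collapse = ", "),
            call. = FALSE)
  }
  out <- vapply(present, function(ph) {
    rowMeans(unclass(m)[, phases == ph, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(rownames(m), present))
  out
}
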