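# Five-phase assignment of a transcript day axis: singletons at 5, 6, 15,
# everything up to day 4 replete, 7..14 starved.
five_phase_of_day <- function(day) {
  ifelse(day <= 4, "NRep",
         ifelse(day == 5, "D5",
                ifelse(day == 6, "D6",
                       ifelse(day == 15, "D15", "NS"))))
}

# Per-phase mean log2FC profiles of the gene programs.
GENE_PROGRAMS <- list(
  up        = c(NRep = 0, D5 = 1.2, D6 = 2.4, NS = 3.0, D15 = 3.2),
  down      = c(NRep = 0, D5 = -1.2, D6 = -2.4, NS = -3.0, D15 = -3.2),
  transient = c(NRep = 0, D5 = 2.5, D6 = 2.5, NS = 0.4, D15 = 0.4),
  d15       = c(NRep = 0, D5 = 0, D6 = 0, NS = 0.3, D15 = 3.0),
  null      = c(NRep = 0, D5 = 0, D6 = 0, NS = 0, D15 = 0))

# Group mix used by default (fractions of n_genes, null takes the rest).
GENE_GROUP_FRACTIONS <- c(up = 0.25, down = 0.25, transient = 0.04, d15 = 0.04)

#' Generate a synthetic transcript + metabolite experiment
#'
#' Builds phase-structured transcript log2FC programs (up-in-NS,
#' down-in-NS, transient-transition, day-15-specific and null genes) with
#' consistent per-gene, per-timepoint FDR values, and a metabolite log2FC
#' matrix containing planted ground truth for the compound-gene screen:
#' `n_true_pairs` compounds tracking a partner gene with a slope drawn in
#' [0.95, 1.05], `n_decoy_pairs` compounds tracking a gene with slope 2
#' (outside the acceptance window), uncorrelated-by-construction decoy
#' compounds (alternating-sign patterns, near-orthogonal to every
#' monotone gene program), and weak compounds that fail the |log2FC| >= 2
#' retention filter.
#'
#' @param n_genes,n_compounds Matrix sizes.
#' @param n_true_pairs Planted unit-slope pairs (<= min(n_genes strong
#'   genes, n_compounds)).
#' @param n_decoy_pairs Planted slope-2 decoy pairs.
#' @param slope_range Interval the planted slopes are drawn from; the
#'   default sits just inside the screen's [0.95, 1.05] acceptance window
#'   so that a planted pair is not lost to estimation noise at the window
#'   edge.
#' @param noise_sd Additive Gaussian noise on every log2FC value.
#' @param seed RNG seed.
#' @param transcript_days,metabolite_days Day axes; metabolite day 10.5
#'   encodes the pooled "10/11" sample, matched downstream to the mean of
#'   transcript days 10 and 11.
#' @param phase_labels Optional factor overriding the five-phase
#'   assignment of `transcript_days`.
#' @param group_fractions Named fractions of genes in the `up`, `down`,
#'   `transient` and `d15` programs (the remainder is null). Set all to 0
#'   for a pure-null experiment.
#' @return list of class `"omics_experiment"`: `transcripts` (log2FC
#'   [omics_matrix()] with an `fdr` attribute), `metabolites` (log2FC
#'   [omics_matrix()]), and `ground_truth` (gene groups, true pairs with
#'   slopes, decoy pairs, decoy/weak compound IDs).
#' @export
#' @examples
#' ex <- generate_omics(n_genes = 50, n_compounds = 20, n_true_pairs = 5)
#' ex$ground_truth$true_pairs
generate_omics <- function(n_genes = 200, n_compounds = 100,
                           n_true_pairs = 20, n_decoy_pairs = 10,
                           slope_range = c(0.975, 1.025),
                           noise_sd = 0.05, seed = 42,
                           transcript_days = c(-2, -1, 2, 4, 5, 6, 7, 8, 10, 11, 15),
                           metabolite_days = c(4, 5, 6, 7, 8, 10.5),
                           phase_labels = NULL,
                           group_fractions = GENE_GROUP_FRACTIONS) {
  check_number(noise_sd, "noise_sd", 0)
  check_number(n_genes, "n_genes", 1)
  check_number(n_compounds, "n_compounds", 1)
  if (is.null(phase_labels)) phase_labels <- five_phase_of_day(transcript_days)
  if (length(phase_labels) != length(transcript_days)) {
    stop_input("`phase_labels` must match `transcript_days`")
  }

  n_strong <- round(n_genes * (group_fractions[["up"]] +
                                 group_fractions[["down"]]))
  if (n_true_pairs + n_decoy_pairs > min(n_strong, n_compounds)) {
    stop_input("not enough strong genes/compounds to plant ",
               n_true_pairs + n_decoy_pairs, " pairs")
  }

  with_seed(seed, {
    counts <- pmax(round(n_genes * group_fractions), 0)
    counts <- c(counts, null = n_genes - sum(counts))
    groups <- rep(names(counts), counts)
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    amp <- stats::runif(n_genes, 0.8, 1.3)

    tmeans <- t(vapply(seq_len(n_genes), function(i) {
      amp[i] * GENE_PROGRAMS[[groups[i]]][phase_labels]
    }, numeric(length(transcript_days))))
    rownames(tmeans) <- gene_ids

    # Pair-partner genes get individualized strong patterns, rejection-
    # sampled so that no partner is confusable with another partner, with a
    # canonical group program, or with the alternating decoy shape inside
    # the screen's shared-timepoint domain (squared correlation <= 0.6,
    # which keeps the cross-pair regression p above 0.05 in the noiseless
    # limit). This guarantees the screen can only retain a planted compound
    # with its own partner gene.
    tmap0 <- default_timepoint_map(metabolite_days, transcript_days)
    map_to_mdays <- function(v) {
      vapply(tmap0, function(dd) mean(v[match(dd, transcript_days)]),
             numeric(1))
    }
    n_partner <- n_true_pairs + n_decoy_pairs
    alt0 <- rep_len(c(1, -1), length(tmap0))
    refs <- lapply(GENE_PROGRAMS[c("up", "down", "transient", "d15")],
                   function(pr) map_to_mdays(pr[phase_labels]))
    refs <- c(refs, list(alt = alt0, alt2 = -alt0))
    refs <- lapply(refs, function(r) r - mean(r))
    partner_rows <- matrix(NA_real_, n_partner, length(transcript_days))
    i_p <- 1L
    while (i_p <= n_partner) {
      # half program-driven (so the DE-gene PCA keeps its low-rank phase
      # structure), half individual, then scaled to a strong amplitude
      base <- GENE_PROGRAMS[[if (i_p %% 2) "up" else "down"]][phase_labels]
      ind <- stats::rnorm(length(transcript_days), 0, 1.2)
      cand <- sqrt(0.5) * base / stats::sd(base) +
        sqrt(0.5) * ind / stats::sd(ind)
      mc <- map_to_mdays(cand)
      cand <- cand * stats::runif(1, 2.0, 2.5) / stats::sd(mc)
      mc <- map_to_mdays(cand)
      if (max(abs(mc)) < 2.4) next  # must clear the metabolite filter
      mc <- mc - mean(mc)
      r2 <- vapply(refs, function(r) {
        s <- sum(r^2) * sum(mc^2)
        if (s == 0) 0 else sum(r * mc)^2 / s
      }, numeric(1))
      if (all(r2 <= 0.6)) {
        partner_rows[i_p, ] <- cand
        refs <- c(refs, list(mc))
        i_p <- i_p + 1L
      }
    }

    partner_idx <- which(groups %in% c("up", "down"))[seq_len(n_partner)]
    tmeans[partner_idx, ] <- partner_rows
    groups[partner_idx] <- "paired"

    tvals <- tmeans + matrix(stats::rnorm(length(tmeans), 0, noise_sd),
                             nrow = n_genes)
    rownames(tvals) <- gene_ids

    # FDR consistent with the planted programs: strongly shifted cells are
    # confidently significant, everything else is not
    sig <- abs(tmeans) >= 1
    fdr <- matrix(stats::runif(length(tmeans), 0.05, 1), nrow = n_genes)
    fdr[sig] <- 10^stats::runif(sum(sig), -8, -3.2)
    rownames(fdr) <- gene_ids

    transcripts <- omics_matrix(tvals, transcript_days, kind = "transcript",
                                log2fc = TRUE, fdr = fdr,
                                control_reference = "pre step-down (NRep) mean")

    # gene patterns seen from the metabolite day axis
    tmap <- default_timepoint_map(metabolite_days, transcript_days)
    gene_at_mdays <- vapply(names(tmap), function(key) {
      cols <- match(tmap[[key]], transcript_days)
      rowMeans(tvals[, cols, drop = FALSE])
    }, numeric(n_genes))

    paired_ids <- gene_ids[partner_idx]
    partner_true <- paired_ids[seq_len(n_true_pairs)]
    partner_decoy <- paired_ids[n_true_pairs + seq_len(n_decoy_pairs)]

    n_t <- length(metabolite_days)
    cmp_ids <- sprintf("cmp%03d", seq_len(n_compounds))
    mvals <- matrix(0, n_compounds, n_t)
    rownames(mvals) <- cmp_ids

    true_slopes <- stats::runif(n_true_pairs, slope_range[1], slope_range[2])
    for (i in seq_len(n_true_pairs)) {
      mvals[i, ] <- true_slopes[i] * gene_at_mdays[partner_true[i], ] +
        stats::rnorm(n_t, 0, noise_sd)
    }
    for (i in seq_len(n_decoy_pairs)) {
      mvals[n_true_pairs + i, ] <- 2 * gene_at_mdays[partner_decoy[i], ] +
        stats::rnorm(n_t, 0, noise_sd)
    }
    # uncorrelated decoys: alternating-sign patterns, near-orthogonal to the
    # monotone phase programs, strong enough to pass the metabolite filter
    n_indep <- max(0, floor(0.3 * n_compounds))
    n_placed <- n_true_pairs + n_decoy_pairs
    n_indep <- min(n_indep, n_compounds - n_placed)
    alt <- rep_len(c(1, -1), n_t)
    for (i in seq_len(n_indep)) {
      a <- stats::runif(1, 2.5, 4) * (if (i %% 2) alt else -alt)
      mvals[n_placed + i, ] <- a + stats::rnorm(n_t, 0, noise_sd)
    }
    # weak compounds: below the |log2FC| >= 2 threshold everywhere
    n_weak <- n_compounds - n_placed - n_indep
    for (i in seq_len(n_weak)) {
      a <- stats::runif(1, 0.3, 1.5) * (if (i %% 2) alt else -alt)
      mvals[n_placed + n_indep + i, ] <- a + stats::rnorm(n_t, 0, noise_sd)
    }

    metabolites <- omics_matrix(mvals, metabolite_days, kind = "metabolite",
                                log2fc = TRUE,
                                control_reference = "pooled pre step-down sample")

    gt <- list(
      gene_groups = stats::setNames(groups, gene_ids),
      true_pairs = data.frame(compound_id = cmp_ids[seq_len(n_true_pairs)],
                              gene_id = partner_true,
                              true_slope = true_slopes,
                              stringsAsFactors = FALSE),
      decoy_pairs = data.frame(
        compound_id = cmp_ids[n_true_pairs + seq_len(n_decoy_pairs)],
        gene_id = partner_decoy,
        true_slope = rep(2, n_decoy_pairs),
        stringsAsFactors = FALSE),
      independent_compounds = cmp_ids[n_placed + seq_len(n_indep)],
      weak_compounds = if (n_weak > 0)
        cmp_ids[n_placed + n_indep + seq_len(n_weak)] else character(0))

    structure(list(transcripts = transcripts, metabolites = metabolites,
                   ground_truth = gt),
              class = "omics_experiment")
  })
}

#' @export
print.omics_experiment <- function(x, ...) {
  cat("Synthetic omics experiment:\n")
  cat("  transcripts:", nrow(x$transcripts), "genes x",
      ncol(x$transcripts), "timepoints\n")
  cat("  metabolites:", nrow(x$metabolites), "compounds x",
      ncol(x$metabolites), "timepoints\n")
  cat("  planted:", nrow(x$ground_truth$true_pairs), "unit-slope pairs,",
      nrow(x$ground_truth$decoy_pairs), "slope-2 decoys\n")
  invisible(x)
}
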