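#' Phase-mean trait profiles of the nitrogen step-down response
#'
#' Each physiological/biochemical trait is modelled as a two-stage logistic
#' switch between its nitrogen-replete (NRep) and nitrogen-starved (NS)
#' phase means: a first step into an intermediate transitional state and a
#' second step, `span` days later, completing the move — the time course
#' passes through a succession of transitory states across days 5-6 rather
#' than jumping. Some traits carry an
#' additional within-NS linear ramp (neutral lipid keeps accumulating, DIC
#' keeps rising) or a transient excursion around the transition
#' (non-photochemical quenching). Phase means are pinned exactly: the
#' intercept and amplitude are solved per trait so that the noiseless means
#' over the NRep sampling days (-2..4) and the NS sampling days (7..15)
#' equal the tabulated phase means.
#'
#' Units: quotas in micrograms per 1e6 cells, DIC in micromolar,
#' fluorescence parameters dimensionless, rETR in relative units.
#'
#' @return A data.frame with one row per trait: `trait`, `m_nrep`, `m_ns`
#'   (phase means), `offset` (switch midpoint relative to the quota
#'   transition time, days), `span` (days between the two logistic
#'   stages), `scale` (per-stage logistic steepness, days), `bump`
#'   (transient-excursion amplitude in trait units), `bump_offset`,
#'   `bump_width` (days), and `ns_ramp` (trait units per day past day 7).
#' @export
trait_profiles <- function() {
  p <- read.table(header = TRUE, text = "
trait          m_nrep  m_ns   offset span  scale bump bump_offset bump_width ns_ramp
dic             4.00    7.00  -0.15  2.40  0.25  0    0           0.7        0.15
neutral_lipid   0.50   47.00   0.15  2.40  0.25  0    0           0.7        8.25
carbohydrate    3.80   12.00   0.10  2.40  0.25  0    0           0.7        0
protein         5.08    2.37   0.15  2.40  0.25  0    0           0.7        0
total_pigment  19.324   7.156 -0.10  2.40  0.25  0    0           0.7        0
chl_a           0.18    0.06  -0.10  2.40  0.25  0    0           0.7        0
chl_c           0.024   0.016 -0.10  2.40  0.25  0    0           0.7        0
carotenoids    19.12    7.08  -0.10  2.40  0.25  0    0           0.7        0
n_int           2.78    0.99  -0.15  2.40  0.25  0    0           0.7        0
c_int          13.99   14.86   0.10  2.40  0.25  0    0           0.7        0
fv_fm           0.65    0.48   0.00  2.40  0.25  0    0           0.7        0
phi_ii          0.60    0.23   0.00  2.40  0.25  0    0           0.7        0
qp              1.00    0.65   0.00  2.40  0.25  0    0           0.7        0
qn              0.20    0.50   0.00  2.40  0.25  0.40 0.00        0.7        0
retr           60.00   25.00   0.00  2.40  0.25  0    0           0.7        0
")
  p
}

# Days used to define the phase means the profiles are pinned to.
SAMPLING_DAYS <- -2:15
NREP_DAYS <- -2:4
NS_DAYS <- 7:15

# Raw (unpinned) shape components of one trait at times t, for a quota
# transition at t_c. The switch is a two-stage logistic: a first step into
# an intermediate transitional state (entered when external nitrate bottoms
# out, about one day before the quota transition) and a second step
# completing the move to the starved state, `span` days later. `bump` adds
# a transient Gaussian excursion around the transition (non-photochemical
# quenching overshoots while the cell re-balances energy dissipation).
trait_shape <- function(t, t_c, prof_row) {
  if (!is.finite(t_c)) {
    return(list(g = rep(0, length(t)), o = rep(0, length(t))))
  }
  ctr <- t_c + prof_row$offset
  c1 <- ctr - prof_row$span / 2
  c2 <- ctr + prof_row$span / 2
  g <- 0.5 * stats::plogis((t - c1) / prof_row$scale) +
    0.5 * stats::plogis((t - c2) / prof_row$scale)
  o <- prof_row$bump *
    exp(-((t - (t_c + prof_row$bump_offset))^2) / (2 * prof_row$bump_width^2)) +
    prof_row$ns_ramp * pmax(0, t - 7)
  list(g = g, o = o)
}

# Pinned trait value at times t. Coefficients are solved on the canonical
# sampling grid so that phase means match m_nrep/m_ns exactly.
trait_value <- function(t, t_c, prof_row) {
  if (!is.finite(t_c)) return(rep(prof_row$m_nrep, length(t)))
  sN <- trait_shape(NREP_DAYS, t_c, prof_row)
  sS <- trait_shape(NS_DAYS, t_c, prof_row)
  gN <- mean(sN$g); gS <- mean(sS$g)
  oN <- mean(sN$o); oS <- mean(sS$o)
  b <- (prof_row$m_ns - prof_row$m_nrep - (oS - oN)) / (gS - gN)
  a <- prof_row$m_nrep - b * gN - oN
  sh <- trait_shape(t, t_c, prof_row)
  a + b * sh$g + sh$o
}

# Macromolecule quota columns carried on the simulated trajectory.
TRAJECTORY_QUOTAS <- c("neutral_lipid", "carbohydrate", "protein",
                       "chl_a", "chl_c", "carotenoids", "c_int")

trait_trajectory <- function(time, transition_time) {
  prof <- trait_profiles()
  prof <- prof[prof$trait %in% TRAJECTORY_QUOTAS, ]
  out <- lapply(seq_len(nrow(prof)), function(i) {
    pmax(trait_value(time, transition_time, prof[i, ]), 0)
  })
  names(out) <- prof$trait
  as.data.frame(out)
}

# Traits reported in the physiological/biochemical trait table (the PCA
# input set: quotas, DIC, fluorescence parameters).
TRAIT_TABLE_SET <- c("dic", "neutral_lipid", "carbohydrate", "protein",
                     "total_pigment", "n_int", "c_int", "fv_fm", "phi_ii",
                     "qp", "qn", "retr")

#' Generate a noisy physiological/biochemical trait table
#'
#' Samples the phase-mean trait trajectories of a simulated experiment at
#' whole sampling days and applies multiplicative Gaussian measurement
#' noise (`value * (1 + N(0, noise_cv))`), clipping quotas at zero. The
#' trait set matches what is fed into the phase-segmentation PCA: DIC,
#' neutral lipid, carbohydrate, soluble protein, total pigment, internal N
#' and C quotas, Fv/Fm, PSII operating yield, qP, qN and rETR.
#'
#' @param traj A [simulate_turbidostat()] trajectory.
#' @param config The configuration to take `noise_cv` and `seed` from;
#'   defaults to the trajectory's own.
#' @param days Sampling days relative to the feed switch; must lie inside
#'   the simulated span.
#' @return A data.frame with a `day` column followed by one column per
#'   trait; attribute `"phase"` holds the generator's ground-truth phase
#'   labels (`NRep`/`transition`/`NS`) and attribute `"noiseless"` the
#'   noise-free values.
#' @export
#' @examples
#' traj <- simulate_turbidostat()
#' tt <- generate_trait_table(traj)
#' tt[tt$day %in% c(-2, 5, 15), c("day", "n_int", "neutral_lipid")]
generate_trait_table <- function(traj, config = traj$config,
                                 days = SAMPLING_DAYS) {
  stopifnot(inherits(traj, "turbidostat_trajectory"))
  span <- range(traj$state$time)
  if (min(days) < span[1] - 1e-9 || max(days) > span[2] + 1e-9) {
    stop_input(sprintf(
      "requested days [%g, %g] outside the simulated span [%g, %g]",
      min(days), max(days), span[1], span[2]))
  }
  t_c <- traj$transition_time
  prof <- trait_profiles()
  prof <- prof[match(TRAIT_TABLE_SET, prof$trait), ]
  clean <- vapply(seq_len(nrow(prof)),
                  function(i) trait_value(days, t_c, prof[i, ]),
                  numeric(length(days)))
  colnames(clean) <- prof$trait
  noisy <- with_seed(config$seed, {
    clean * (1 + matrix(stats::rnorm(length(clean), 0, config$noise_cv),
                        nrow = nrow(clean)))
  })
  noisy <- pmax(noisy, 0)
  out <- data.frame(day = days, noisy)
  attr(out, "phase") <- ground_truth_phases(days, t_c)
  attr(out, "noiseless") <- clean
  out
}

# Ground-truth phase labels implied by the generator: the two sampling days
# bracketing the quota transition are the transition phase, everything
# earlier is NRep, everything later NS.
ground_truth_phases <- function(days, t_c) {
  if (!is.finite(t_c)) return(rep("NRep", length(days)))
  first_trans <- floor(t_c - 0.5)
  ifelse(days < first_trans, "NRep",
         ifelse(days > first_trans + 1, "NS", "transition"))
}
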