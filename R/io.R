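#' Read a trait table or omics matrix from TSV/CSV
#'
#' The delimiter is sniffed from the extension (`.csv` comma, anything
#' else tab). Trait tables have a `day` first column; omics matrices have
#' feature IDs in the first column and day-labelled headers
#' (`D-2` ... `D15`, `D10/11`). Ragged rows, duplicate IDs and
#' non-numeric cells raise schema errors naming the offender.
#'
#' @param path File path.
#' @param kind `"traits"`, `"transcript"` or `"metabolite"`.
#' @param log2fc For omics kinds: are the stored values log2 fold changes?
#' @return A trait data.frame or an [omics_matrix()].
#' @export
read_matrix <- function(path, kind = c("traits", "transcript", "metabolite"),
                        log2fc = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_input("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (kind == "traits") {
    if (names(df)[1] != "day") stop_input("trait table must start with `day`")
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(bad)) stop_input("non-numeric column(s): ",
                                paste(bad, collapse = ", "))
    return(df)
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop_input("duplicate feature ID(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- colnames(vals)[!apply(vals, 2, function(v)
      all(!is.na(suppressWarnings(as.numeric(v)))))]
    stop_input("non-numeric cell(s) in column(s): ",
               paste(bad, collapse = ", "))
  }
  rownames(vals) <- ids
  tp <- parse_day_label(colnames(vals))
  if (anyNA(tp)) {
    stop_input("unparseable day header(s): ",
               paste(colnames(vals)[is.na(tp)], collapse = ", "))
  }
  o <- order(tp)
  omics_matrix(vals[, o, drop = FALSE], tp[o], kind = kind, log2fc = log2fc)
}

#' Write a trait table or omics matrix as TSV/CSV
#'
#' Numeric formatting is locale-independent (C-style `.` decimal, up to 15
#' significant digits), so a write/read cycle round-trips.
#'
#' @param x Trait data.frame or [omics_matrix()].
#' @param path Output path; extension selects the delimiter.
#' @param id_column Header of the feature-ID column for omics matrices.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_column = "feature_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (inherits(x, "omics_matrix")) {
    df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_column
  } else {
    df <- as.data.frame(x)
  }
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a turbidostat experiment, then runs every downstream stage in
#' order: overflow-based dilution/division rates, stored-energy time
#' course, pigment spectra generation and quantification, trait PCA and
#' phase segmentation, transcript and metabolite retention filters, the
#' compound-gene pair screen, and five-phase averaged matrices. All
#' artifacts are written as TSV/JSON under `out_dir` together with a run
#' manifest (config snapshot, seed, output checksums); a rerun with the
#' same config reproduces identical checksums.
#'
#' @param config A [turbidostat_config()], or a path to a YAML/JSON file
#'   of its fields.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = turbidostat_config(), out_dir = tempfile("nitrophase_run_")) {
  if (is.character(config)) {
    fields <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    config <- do.call(turbidostat_config, fields)
  }
  stopifnot(inherits(config, "turbidostat_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  traj <- stage("simulate", simulate_turbidostat(config))
  traits <- stage("traits", generate_trait_table(traj))
  growth <- stage("growth", dilution_series(traj))
  energy <- stage("energy", energy_timecourse(traits))

  spectra <- stage("pigments", {
    dens <- vapply(traits$day, function(d) {
      traj$state$x[which.min(abs(traj$state$time - d))]
    }, numeric(1))
    # split total pigment into components at the replete-phase ratios,
    # convert per-cell quotas back to culture concentrations, make spectra
    pigs <- data.frame(
      chl_a = traits$total_pigment * 0.18 / 19.324,
      chl_c = traits$total_pigment * 0.024 / 19.324,
      carotenoids = traits$total_pigment * 19.12 / 19.324)
    conc <- vapply(pigs, function(q) q * dens / 1e6, numeric(nrow(traits)))
    m <- generate_spectrum(conc[, "chl_a"], conc[, "chl_c"],
                           conc[, "carotenoids"], baseline_a750 = 0.01)
    cbind(day = traits$day, m, quantify_pigments(m)[, 1:3])
  })

  phases <- stage("phases", {
    z <- standardize_traits(traits)
    pca <- run_pca(z)
    lab <- segment_phases(pca, traits$day)
    five <- five_phase_labels(lab, traits$day)
    list(pca = pca, labels = lab, five = five)
  })

  omics <- stage("omics", {
    ex <- generate_omics(noise_sd = 0.05, seed = config$seed)
    de <- filter_transcripts(ex$transcripts)
    met <- filter_metabolites(ex$metabolites)
    screen <- pair_screen(subset_features(ex$metabolites, met),
                          subset_features(ex$transcripts, de))
    tf <- five_phase_of_day(om_timepoints(ex$transcripts))
    pa <- phase_average(ex$transcripts, tf)
    list(experiment = ex, de_genes = de, metabolites = met,
         screen = screen, phase_means = pa)
  })

  # write artifacts
  fp <- function(f) file.path(out_dir, f)
  write_matrix(data.frame(time = traj$state$time,
                          signif(traj$state[, -1], 6)), fp("trajectory.tsv"))
  write_matrix(traits, fp("traits.tsv"))
  write_matrix(growth, fp("growth.tsv"))
  write_matrix(energy, fp("energy.tsv"))
  write_matrix(spectra, fp("spectra.tsv"))
  write_matrix(data.frame(day = traits$day,
                          label = as.character(phases$labels),
                          five_phase = as.character(phases$five)),
               fp("phases.tsv"))
  write_matrix(as.data.frame(omics$screen), fp("pair_screen.tsv"))
  write_matrix(omics$experiment$transcripts, fp("transcripts_log2fc.tsv"),
               id_column = "gene_id")
  write_matrix(omics$experiment$metabolites, fp("metabolites_log2fc.tsv"),
               id_column = "compound_id")
  jsonlite::write_json(omics$experiment$ground_truth,
                       fp("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)

  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("nitrophase")),
    seed = config$seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(trajectory = traj, traits = traits, growth = growth,
                 energy = energy, spectra = spectra, phases = phases,
                 omics = omics, manifest = manifest, out_dir = out_dir))
}
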