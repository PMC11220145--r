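#' Load a packaged simulation scenario
#'
#' Scenarios are YAML files describing complete simulation configurations.
#' The package ships: `single-molecule-33` (pooled single-molecule stutter
#' assay on a 33 CAG template), `family-A-ten-tissues` (ten brain regions
#' of a 33 CAG carrier with tissue-specific somatic expansion),
#' `IA-cohort-135`, `RP-cohort-37`, `FP-cohort-88` (cohorts generated from
#' the per-category regression models at the published sample sizes) and
#' `control-vs-symptomatic` (two intermediate-allele groups sharing one
#' generating model).
#'
#' @param name A shipped scenario name (without extension) or a path to a
#'   scenario YAML file.
#' @return A list of class `"cag_scenario"`.
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) name
          else system.file("extdata", "scenarios", paste0(name, ".yaml"),
                           package = "cagmosaic")
  if (!nzchar(path) || !file.exists(path))
    cag_error("missing_file", sprintf("scenario not found: %s", name))
  sc <- yaml::read_yaml(path)
  if (is.null(sc$type))
    cag_error("schema", "scenario file has no `type` field")
  sc$name <- sc$name %||% sub("\\.ya?ml$", "", basename(path))
  structure(sc, class = "cag_scenario")
}

scenario_allele <- function(x) do.call(allele_structure, x)

scenario_stutter <- function(sc) {
  if (is.null(sc$stutter)) stutter_params()
  else do.call(stutter_params, sc$stutter)
}

#' Run a simulation scenario
#'
#' Dispatches on the scenario `type`:
#' * `single_molecule` -> [simulate_molecule_pcr()];
#' * `tissue_panel` -> one [simulate_tissue_reads()] per tissue (sequential
#'   draws from a single seeded RNG stream, so a scenario run is
#'   reproducible end to end);
#' * `cohort` -> [simulate_cohort()];
#' * `group_comparison` -> one cohort per group, bound into one table.
#'
#' @param scenario A `"cag_scenario"` from [load_scenario()], or a name.
#' @param seed RNG seed for the whole scenario run.
#' @param depth Override the scenario's per-sample read depth (optional).
#' @param output_dir Optional directory: FASTQ (read scenarios) or cohort
#'   TSV (cohort scenarios) are written there.
#' @return Scenario-dependent: the simulator's return value, or for
#'   `tissue_panel` a named list of `"tissue_sim"` objects plus `targets`.
#' @export
simulate_scenario <- function(scenario, seed = NULL, depth = NULL,
                              output_dir = NULL) {
  if (!inherits(scenario, "cag_scenario")) scenario <- load_scenario(scenario)
  if (!is.null(output_dir) &&
      !dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  switch(
    scenario$type,
    single_molecule = {
      simulate_molecule_pcr(
        template = scenario_allele(scenario$template),
        params = scenario_stutter(scenario),
        n_reads = scenario$n_reads,
        n_reactions = scenario$n_reactions %||% 1L,
        error_rate = scenario$error_rate %||% 0.001,
        fastq = if (!is.null(output_dir))
          file.path(output_dir, paste0(scenario$name, ".fastq")),
        sample_id = scenario$name
      )
    },
    tissue_panel = {
      alleles <- list(short = scenario_allele(scenario$alleles$short),
                      long = scenario_allele(scenario$alleles$long))
      params <- scenario_stutter(scenario)
      depth <- depth %||% scenario$depth
      sims <- lapply(names(scenario$tissues), function(tis) {
        cfg <- scenario$tissues[[tis]]
        simulate_tissue_reads(
          alleles = alleles,
          mosaicism = mosaicism_model(unlist(cfg$expansion_freqs)),
          params = params, depth = depth,
          error_rate = scenario$error_rate %||% 0.001,
          allele_balance = scenario$allele_balance %||% 0.5,
          sample_id = tis, tissue = tis,
          fastq = if (!is.null(output_dir))
            file.path(output_dir, paste0(tis, ".fastq"))
        )
      })
      names(sims) <- names(scenario$tissues)
      targets <- vapply(scenario$tissues, function(cfg)
        cfg$target_ratio %||% NA_real_, 0)
      list(tissues = sims, targets = targets, alleles = alleles,
           params = params, window = scenario$window %||% 10L)
    },
    cohort = {
      sim <- simulate_cohort(
        n_samples = scenario$n_samples,
        cag_range = unlist(scenario$cag_range),
        coeffs = scenario$coefficients,
        noise_sd = scenario$noise_sd,
        age_range = unlist(scenario$age_range %||% c(20, 90)),
        group = scenario$group %||% "unknown",
        cag_weights = unlist(scenario$cag_weights),
        id_prefix = scenario$id_prefix %||% "S"
      )
      if (!is.null(output_dir))
        write_cohort_tsv(sim$records,
                         file.path(output_dir, paste0(scenario$name, ".tsv")),
                         provenance = c(scenario = scenario$name))
      sim
    },
    group_comparison = {
      sims <- lapply(names(scenario$groups), function(g) {
        cfg <- scenario$groups[[g]]
        simulate_cohort(
          n_samples = cfg$n_samples,
          cag_range = unlist(scenario$cag_range),
          coeffs = scenario$coefficients,
          noise_sd = scenario$noise_sd,
          age_range = unlist(scenario$age_range %||% c(20, 90)),
          group = g,
          cag_weights = unlist(scenario$cag_weights),
          id_prefix = toupper(substr(g, 1, 1))
        )
      })
      records <- do.call(rbind, lapply(sims, `[[`, "records"))
      if (!is.null(output_dir))
        write_cohort_tsv(records,
                         file.path(output_dir, paste0(scenario$name, ".tsv")),
                         provenance = c(scenario = scenario$name))
      list(records = records, truth = lapply(sims, `[[`, "truth"))
    },
    cag_error("schema", sprintf("unknown scenario type: %s", scenario$type))
  )
}

#' Run the read-level pipeline on one simulated tissue sample
#'
#' Convenience wrapper used by tests and the acceptance machinery:
#' decompose the simulated reads, genotype the sample, and compute the
#' expansion profile of the long (unstable) allele.
#'
#' @param sim A `"tissue_sim"` from [simulate_tissue_reads()].
#' @param locus Locus configuration.
#' @param window Expansion-counting window.
#' @return An `"expansion_profile"` for the long allele.
#' @export
profile_from_sim <- function(sim, locus = htt_locus(), window = 10L) {
  stopifnot(inherits(sim, "tissue_sim"))
  calls <- anchor_and_decompose(sim$reads, locus, read_ids = sim$read_ids)
  gt <- genotype_sample(calls, locus)
  compute_expansion_ratio(gt, gt$allele_long, window = window,
                          sample_id = sim$sample_id, tissue = sim$tissue,
                          allele_role = "long")
}
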