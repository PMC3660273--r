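#' Kit-specific FFPET degradation profile
#'
#' Describes how a given RNA amplification workflow degrades the probe-level
#' signal of formalin-fixed, paraffin-embedded tissue (FFPET) relative to the
#' matched fresh-frozen (FF) section. The model is additive in log2 space and
#' linear in the probe's distance from the transcript 3' end: a probe at
#' distance `d` nt loses `global_attenuation + three_prime_decay * d` log2
#' units of signal, receives extra Gaussian noise with SD `extra_noise_sd`
#' (log2), and with probability `dropout_prob` is replaced by a
#' background-only measurement. An all-zero profile leaves the FFPET signal
#' distribution identical to FF.
#'
#' @param kit_label Character scalar naming the kit (e.g. `"nugen"`).
#' @param three_prime_decay Non-negative log2 attenuation per nucleotide of
#'   distance from the transcript 3' end.
#' @param extra_noise_sd Non-negative SD (log2 units) of additional
#'   measurement noise specific to the FFPET workflow.
#' @param dropout_prob Probability in `[0,1]` that a probe measurement is
#'   lost entirely and replaced by background signal.
#' @param global_attenuation Non-negative uniform log2 signal loss.
#' @return An object of class `degradation_profile`.
#' @export
degradation_profile <- function(kit_label,
                                three_prime_decay = 0,
                                extra_noise_sd = 0,
                                dropout_prob = 0,
                                global_attenuation = 0) {
  stopifnot(is.character(kit_label), length(kit_label) == 1L, nzchar(kit_label))
  for (nm in c("three_prime_decay", "extra_noise_sd", "dropout_prob",
               "global_attenuation")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("configuration error: field '", nm, "' must be a non-negative number",
           call. = FALSE)
    }
  }
  if (dropout_prob > 1) {
    stop("configuration error: field 'dropout_prob' must lie in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(kit_label = kit_label,
         three_prime_decay = three_prime_decay,
         extra_noise_sd = extra_noise_sd,
         dropout_prob = dropout_prob,
         global_attenuation = global_attenuation),
    class = "degradation_profile"
  )
}

#' Default kit degradation presets
#'
#' Three presets emulating the qualitative quality ordering of common FFPET
#' amplification workflows: `nugen` (mild degradation), `affy2c` (moderate)
#' and `wta` (strong). The numerical values are free simulator parameters
#' chosen to produce clearly separated cohort quality, not measured kit
#' properties.
#'
#' @return Named list of [degradation_profile()] objects.
#' @export
default_kit_profiles <- function() {
  list(
    nugen  = degradation_profile("nugen",  three_prime_decay = 0.0015,
                                 extra_noise_sd = 0.3, dropout_prob = 0.02,
                                 global_attenuation = 0.5),
    affy2c = degradation_profile("affy2c", three_prime_decay = 0.003,
                                 extra_noise_sd = 0.6, dropout_prob = 0.05,
                                 global_attenuation = 1.0),
    wta    = degradation_profile("wta",    three_prime_decay = 0.006,
                                 extra_noise_sd = 1.2, dropout_prob = 0.12,
                                 global_attenuation = 2.0)
  )
}

sim_config_fields <- c(
  "seed", "n_genes", "transcript_length_range", "probe_sets_per_gene",
  "probes_per_set", "probe_length", "frac_nonmatching_probes",
  "frac_crosshyb_probes", "n_complete_mismatch_sets", "n_pairs_per_group",
  "frac_de_genes", "effect_range", "frac_silent_genes", "kit_profiles",
  "background_mean", "background_sd", "probe_affinity_sd",
  "measurement_sd_ff", "baseline_mean", "baseline_sd", "tissue_sd",
  "control_transcript_length", "control_probe_spacing"
)

#' Simulation configuration for a matched FF/FFPET cohort
#'
#' Bundles every tunable of the synthetic-data generator: the reference
#' transcriptome, the flawed array design, the biological contrast
#' (estrogen-receptor status of breast tumors, `n_pairs_per_group` ER+ and
#' ER- matched pairs) and the kit-specific degradation profiles. Defaults
#' describe a desk-scale cohort of 16 matched tumor pairs (8 ER+, 8 ER-)
#' with ER-driven differential expression in a fifth of the genes.
#'
#' All randomness downstream is controlled by `seed`: sub-seeds are derived
#' by fixed offsets (reference `seed`, array design `seed + 1`, cohort
#' latent/FF draws `seed + 2`, kit `i` extra noise `seed + 100 + i`), using
#' R's Mersenne-Twister generator with inversion for normal deviates, so a
#' fixed seed gives byte-identical outputs across platforms.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of simulated genes (one transcript each), excluding
#'   the dedicated 3'/5' QC control transcript.
#' @param transcript_length_range Integer pair, min/max transcript length (nt).
#' @param probe_sets_per_gene Named numeric vector of probabilities for the
#'   number of probe sets interrogating a gene; names are the counts.
#' @param probes_per_set Probes per probe set (default 11).
#' @param probe_length Probe length in nt (default 25).
#' @param frac_nonmatching_probes Fraction of probes replaced by random
#'   sequences absent from the reference (Hamming distance > 3 everywhere).
#' @param frac_crosshyb_probes Fraction of probes made cross-hybridizing by
#'   copying their target subsequence into a second gene's transcript.
#' @param n_complete_mismatch_sets Number of whole probe sets of
#'   verified-absent probes appended as blank controls.
#' @param n_pairs_per_group Matched tumor pairs per ER group (default 8).
#' @param frac_de_genes Fraction of genes with a true ER effect `|delta| > 1`.
#' @param effect_range Magnitude range (log2) of the planted signed effects.
#' @param frac_silent_genes Fraction of non-DE genes not expressed in the
#'   tissue; their probes emit background only.
#' @param kit_profiles Named list of [degradation_profile()] objects; names
#'   must equal each profile's `kit_label`.
#' @param background_mean,background_sd Mean and SD of the additive optical
#'   background (linear intensity scale).
#' @param probe_affinity_sd SD (log2) of the fixed per-probe affinity.
#' @param measurement_sd_ff SD (log2) of FF measurement noise.
#' @param baseline_mean,baseline_sd Mean and SD (log2) of per-gene baseline
#'   expression.
#' @param tissue_sd SD (log2) of per-tumor biological noise, shared by the
#'   mirrored FF and FFPET sections of a tumor.
#' @param control_transcript_length Length (nt) of the dedicated intact-RNA
#'   QC control transcript, tiled densely with probes.
#' @param control_probe_spacing Spacing (nt) between consecutive control
#'   probe start positions.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       transcript_length_range = c(600L, 1200L),
                       probe_sets_per_gene = c("1" = 0.70, "2" = 0.25, "3" = 0.05),
                       probes_per_set = 11L,
                       probe_length = 25L,
                       frac_nonmatching_probes = 0.05,
                       frac_crosshyb_probes = 0.03,
                       n_complete_mismatch_sets = 60L,
                       n_pairs_per_group = 8L,
                       frac_de_genes = 0.2,
                       effect_range = c(1.2, 3),
                       frac_silent_genes = 0.3,
                       kit_profiles = default_kit_profiles(),
                       background_mean = 50,
                       background_sd = 10,
                       probe_affinity_sd = 0.3,
                       measurement_sd_ff = 0.25,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       tissue_sd = 0.3,
                       control_transcript_length = 1998L,
                       control_probe_spacing = 18L) {
  cfg <- mget(sim_config_fields)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

cfg_error <- function(field, msg) {
  stop("configuration error: field '", field, "' ", msg, call. = FALSE)
}

validate_sim_config <- function(cfg) {
  num1 <- function(field, lo = -Inf, hi = Inf, int = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      cfg_error(field, "must be a single number")
    }
    if (v < lo || v > hi) {
      cfg_error(field, sprintf("must lie in [%s, %s]", lo, hi))
    }
    if (int && v != round(v)) cfg_error(field, "must be an integer")
    invisible(v)
  }
  num1("seed", int = TRUE)
  num1("n_genes", lo = 2, int = TRUE)
  tlr <- cfg$transcript_length_range
  if (!is.numeric(tlr) || length(tlr) != 2L || any(is.na(tlr)) ||
      tlr[1] > tlr[2] || any(tlr != round(tlr))) {
    cfg_error("transcript_length_range", "must be an integer pair (min, max)")
  }
  psg <- cfg$probe_sets_per_gene
  if (!is.numeric(psg) || is.null(names(psg)) ||
      any(is.na(suppressWarnings(as.integer(names(psg))))) ||
      any(psg < 0) || abs(sum(psg) - 1) > 1e-8) {
    cfg_error("probe_sets_per_gene",
              "must be a named probability vector summing to 1")
  }
  num1("probes_per_set", lo = 1, int = TRUE)
  num1("probe_length", lo = 1, int = TRUE)
  if (cfg$probe_length > tlr[1]) {
    cfg_error("probe_length", "must not exceed the minimum transcript length")
  }
  for (f in c("frac_nonmatching_probes", "frac_crosshyb_probes",
              "frac_de_genes", "frac_silent_genes")) {
    num1(f, lo = 0, hi = 1)
  }
  num1("n_complete_mismatch_sets", lo = 0, int = TRUE)
  num1("n_pairs_per_group", lo = 2, int = TRUE)
  er <- cfg$effect_range
  if (!is.numeric(er) || length(er) != 2L || any(is.na(er)) ||
      er[1] > er[2] || er[1] <= 0) {
    cfg_error("effect_range", "must be a positive (min, max) magnitude pair")
  }
  kp <- cfg$kit_profiles
  if (!is.list(kp) || length(kp) == 0 || is.null(names(kp)) ||
      !all(vapply(kp, inherits, logical(1), "degradation_profile"))) {
    cfg_error("kit_profiles", "must be a named list of degradation_profile objects")
  }
  labs <- vapply(kp, `[[`, character(1), "kit_label")
  if (!identical(unname(labs), names(kp))) {
    cfg_error("kit_profiles", "names must equal each profile's kit_label")
  }
  for (f in c("background_mean", "background_sd", "probe_affinity_sd",
              "measurement_sd_ff", "baseline_sd", "tissue_sd")) {
    num1(f, lo = 0)
  }
  num1("baseline_mean")
  num1("control_transcript_length", lo = 3 * cfg$probe_length, int = TRUE)
  num1("control_probe_spacing", lo = 1, int = TRUE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Matched FF/FFPET cohort simulation config\n")
  cat(sprintf("  %d genes, %d+%d matched pairs (ER+/ER-), %d kits (%s)\n",
              x$n_genes, x$n_pairs_per_group, x$n_pairs_per_group,
              length(x$kit_profiles),
              paste(names(x$kit_profiles), collapse = ", ")))
  cat(sprintf("  DE fraction %.2f, |effect| in [%.2f, %.2f] log2; seed %d\n",
              x$frac_de_genes, x$effect_range[1], x$effect_range[2], x$seed))
  invisible(x)
}

## Deterministic RNG setup shared by all generator stages.
set_sim_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file maps 1:1 to the arguments of [sim_config()]; `kit_profiles` is a
#' mapping from kit label to the degradation-profile fields. Missing fields
#' take the [sim_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_sim_config(raw)
}

as_sim_config <- function(raw) {
  stopifnot(is.list(raw))
  unknown <- setdiff(names(raw), sim_config_fields)
  if (length(unknown)) {
    stop("configuration error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$kit_profiles)) {
    raw$kit_profiles <- lapply(names(raw$kit_profiles), function(nm) {
      p <- raw$kit_profiles[[nm]]
      if (inherits(p, "degradation_profile")) return(p)
      do.call(degradation_profile, c(list(kit_label = nm), p))
    })
    names(raw$kit_profiles) <- vapply(raw$kit_profiles, `[[`, character(1),
                                      "kit_label")
  }
  if (!is.null(raw$probe_sets_per_gene) && is.list(raw$probe_sets_per_gene)) {
    raw$probe_sets_per_gene <- unlist(raw$probe_sets_per_gene)
  }
  do.call(sim_config, raw)
}
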