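#' Configuration for the synthetic PM cohort generator
#'
#' Describes a paired tumour/normal TMT-style cohort with a planted
#' tumour-vs-normal differential set, a planted PM-associated module with
#' controlled per-protein signal-to-noise, and survival times driven by a
#' weighted score over the module. Defaults mirror the study design the
#' pipeline targets: 14 PM and 6 PM-free subjects, one tumour and one paired
#' normal sample each, ~2000 quantified proteins and a 20-protein module.
#'
#' @param n_proteins number of proteins simulated.
#' @param n_pm_subjects,n_pmfree_subjects subjects with / without peritoneal
#'   metastasis; each contributes a tumour (T) and a paired normal (N) sample.
#' @param n_dep number of planted tumour-vs-normal differential proteins.
#' @param module_size size of the planted PM-associated module (a subset of
#'   the differential proteins).
#' @param target_snr per-protein signal-to-noise of the module between PM and
#'   PM-free tumours: the planted shift is
#'   `delta_p = target_snr * (sd_PM + sd_PMfree)`.
#' @param tumor_effect_range range (log2 units) of the planted tumour-vs-normal
#'   shifts; signs are random per protein.
#' @param tech_noise_sd per-measurement technical noise SD in log2 units.
#' @param beta_hazard log-hazard per unit of the standardized planted score.
#' @param censor_frac target fraction of censored subjects.
#' @param external_n sample size of the synthetic external transcriptome cohort.
#' @param external_attenuation shrinkage (0-1) applied to module effects in the
#'   external transcriptome relative to the proteome.
#' @param frac_low_peptide fraction of proteins given a single unique peptide,
#'   to exercise the >= 2 unique-peptide filter.
#' @param base_mean,base_sd log2 baseline abundance distribution
#'   (per-protein mean ~ Normal(base_mean, base_sd)).
#' @param ext_noise_sd noise SD of the external transcriptome (z-like scale).
#' @param baseline_hazard baseline exponential hazard (per month).
#' @param seed integer seed; the generator is fully reproducible given it.
#' @return A validated list of class `pm_sim_config`.
#' @export
pm_sim_config <- function(n_proteins = 2000, n_pm_subjects = 14,
                          n_pmfree_subjects = 6, n_dep = 300,
                          module_size = 20, target_snr = 1.2,
                          tumor_effect_range = c(0.8, 2.0),
                          tech_noise_sd = 0.5, beta_hazard = 0.7,
                          censor_frac = 0.3, external_n = 300,
                          external_attenuation = 0.6,
                          frac_low_peptide = 0.05,
                          base_mean = 25, base_sd = 3, ext_noise_sd = 1,
                          baseline_hazard = log(2) / 24, seed = 1L) {
  cfg <- list(n_proteins = n_proteins, n_pm_subjects = n_pm_subjects,
              n_pmfree_subjects = n_pmfree_subjects, n_dep = n_dep,
              module_size = module_size, target_snr = target_snr,
              tumor_effect_range = tumor_effect_range,
              tech_noise_sd = tech_noise_sd, beta_hazard = beta_hazard,
              censor_frac = censor_frac, external_n = external_n,
              external_attenuation = external_attenuation,
              frac_low_peptide = frac_low_peptide, base_mean = base_mean,
              base_sd = base_sd, ext_noise_sd = ext_noise_sd,
              baseline_hazard = baseline_hazard, seed = seed)
  assert_count(cfg$n_proteins, "n_proteins")
  assert_count(cfg$n_pm_subjects, "n_pm_subjects")
  assert_count(cfg$n_pmfree_subjects, "n_pmfree_subjects")
  assert_count(cfg$n_dep, "n_dep", min = 0)
  assert_count(cfg$module_size, "module_size", min = 0)
  assert_count(cfg$external_n, "external_n", min = 2)
  if (cfg$module_size > cfg$n_dep) stop_field("module_size", "must be <= n_dep")
  if (cfg$n_dep > cfg$n_proteins) stop_field("n_dep", "must be <= n_proteins")
  if (!is.numeric(cfg$target_snr) || cfg$target_snr <= 0) {
    stop_field("target_snr", "must be > 0")
  }
  if (length(cfg$tumor_effect_range) != 2 || any(cfg$tumor_effect_range < 0) ||
      diff(cfg$tumor_effect_range) < 0) {
    stop_field("tumor_effect_range", "must be an increasing nonnegative pair")
  }
  if (cfg$tech_noise_sd <= 0) stop_field("tech_noise_sd", "must be > 0")
  if (cfg$censor_frac < 0 || cfg$censor_frac >= 1) {
    stop_field("censor_frac", "must be in [0, 1)")
  }
  if (cfg$external_attenuation < 0 || cfg$external_attenuation > 1) {
    stop_field("external_attenuation", "must be in [0, 1]")
  }
  if (cfg$frac_low_peptide < 0 || cfg$frac_low_peptide >= 1) {
    stop_field("frac_low_peptide", "must be in [0, 1)")
  }
  assert_count(cfg$seed, "seed", min = 0)
  class(cfg) <- "pm_sim_config"
  cfg
}

#' Simulate a paired tumour/normal proteomic cohort with planted structure
#'
#' Generates raw (linear-scale) protein intensities for one tumour and one
#' paired normal sample per subject. Planted tumour-vs-normal differential
#' proteins are shifted in all tumours; a planted module (a subset of those) is
#' additionally shifted in PM tumours by `target_snr * (sd_PM + sd_PMfree)` so
#' its per-protein signal-to-noise between PM and PM-free tumours is
#' controlled. Overall survival is drawn from an exponential model whose
#' log-hazard is `beta_hazard` times the standardized planted module score;
#' censoring is independent Uniform(0, c) with c tuned to the target fraction.
#'
#' @param config a [pm_sim_config()].
#' @return A list with components
#'   \describe{
#'     \item{expr}{raw-state [expr_matrix()], proteins x samples;}
#'     \item{peptides}{data.frame `protein_id`, `unique_peptides`;}
#'     \item{samples}{per-sample annotation data.frame (see
#'       [read_samples_csv()] for columns);}
#'     \item{truth}{ground truth: `dep_ids`, `module_ids`, `true_weights`,
#'       `tumor_effects`, `pm_effects`, `beta_hazard`, `group_labels`,
#'       `true_score`, `protein_ids`.}
#'   }
#' @examples
#' sim <- simulate_cohort(pm_sim_config(n_proteins = 100, n_dep = 20,
#'                                      module_size = 5, seed = 1))
#' sim$expr
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "pm_sim_config")) config <- do.call(pm_sim_config, config)
  with_seed(config$seed, {
    P <- config$n_proteins
    n_pm <- config$n_pm_subjects
    n_con <- config$n_pmfree_subjects
    n_sub <- n_pm + n_con
    pid <- sprintf("P%04d", seq_len(P))
    subj <- sprintf("S%02d", seq_len(n_sub))
    pm_status <- c(rep(1L, n_pm), rep(0L, n_con))

    dep_ids <- if (config$n_dep > 0) sort(sample(pid, config$n_dep)) else character(0)
    module_ids <- if (config$module_size > 0) sort(sample(dep_ids, config$module_size)) else character(0)

    tumor_effects <- stats::setNames(
      sample(c(-1, 1), length(dep_ids), replace = TRUE) *
        stats::runif(length(dep_ids), config$tumor_effect_range[1],
                     config$tumor_effect_range[2]),
      dep_ids)
    # the planted module emulates a co-regulated program: consistent
    # direction in the tumour-vs-normal contrast as well as the PM shift
    tumor_effects[module_ids] <- abs(tumor_effects[module_ids])
    # both phenotype groups share the technical noise SD, so the planted
    # between-group shift achieving `target_snr` is snr * 2 * tech_noise_sd;
    # the shift is coherent (same direction) across the module, as in a
    # co-regulated expression program
    delta <- config$target_snr * 2 * config$tech_noise_sd
    pm_effects <- stats::setNames(rep(delta, length(module_ids)), module_ids)

    mu <- stats::rnorm(P, config$base_mean, config$base_sd)
    names(mu) <- pid

    t_cols <- paste0(subj, "_T")
    n_cols <- paste0(subj, "_N")
    x <- matrix(stats::rnorm(P * 2 * n_sub, 0, config$tech_noise_sd),
                nrow = P, ncol = 2 * n_sub,
                dimnames = list(pid, c(t_cols, n_cols)))
    x <- x + mu
    x[dep_ids, t_cols] <- x[dep_ids, t_cols] + tumor_effects[dep_ids]
    pm_t_cols <- t_cols[pm_status == 1L]
    if (length(module_ids)) {
      x[module_ids, pm_t_cols] <- x[module_ids, pm_t_cols] + pm_effects[module_ids]
    }
    expr <- expr_matrix(2^x, "raw")

    n_low <- round(config$frac_low_peptide * P)
    pept <- 2L + stats::rpois(P, 4)
    if (n_low > 0) pept[sample.int(P, n_low)] <- 1L
    peptides <- data.frame(protein_id = pid, unique_peptides = pept,
                           stringsAsFactors = FALSE)

    # weight signs follow the planted PM direction so the prognostic score a
    # PM classifier learns is the one that drives survival
    true_weights <- stats::setNames(
      sign(pm_effects[module_ids]) *
        stats::runif(length(module_ids), 0.5, 1.5), module_ids)

    # subject-level planted score from tumour log2 values of module proteins
    if (length(module_ids)) {
      xt <- x[module_ids, t_cols, drop = FALSE]
      zt <- (xt - rowMeans(xt)) / apply(xt, 1, stats::sd)
      score <- as.numeric(crossprod(zt, true_weights[module_ids]))
    } else {
      score <- rep(0, n_sub)
    }
    if (stats::sd(score) > 0) score <- (score - mean(score)) / stats::sd(score)
    names(score) <- subj

    ev_time <- stats::rexp(n_sub, rate = config$baseline_hazard *
                             exp(config$beta_hazard * score))
    if (config$censor_frac > 0) {
      cens_p <- function(cc) mean(pmin(ev_time / cc, 1)) - config$censor_frac
      upper <- max(ev_time) * 100
      cc <- if (cens_p(upper) > 0) upper else
        stats::uniroot(cens_p, c(1e-6, upper))$root
      cens <- stats::runif(n_sub, 0, cc)
      os_event <- as.integer(ev_time <= cens)
      os_months <- pmin(ev_time, cens)
    } else {
      os_event <- rep(1L, n_sub)
      os_months <- ev_time
    }

    # Syn/Meta split annotated at the enrolment proportion (labels only)
    n_syn <- round(n_pm * 13 / 19)
    group <- c(rep("Syn", n_syn), rep("Meta", n_pm - n_syn), rep("Con", n_con))
    age <- pmin(pmax(round(stats::rnorm(n_sub, 60, 10)), 30), 85)
    stage <- sample(2:4, n_sub, replace = TRUE, prob = c(0.2, 0.5, 0.3))

    per_sub <- data.frame(subject_id = subj, group = group,
                          pm_status = pm_status, os_months = os_months,
                          os_event = os_event, age = age, stage = stage,
                          stringsAsFactors = FALSE)
    samples <- rbind(
      data.frame(sample_id = t_cols, tissue = "T", per_sub,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = n_cols, tissue = "N", per_sub,
                 stringsAsFactors = FALSE))
    samples <- samples[, c("sample_id", "subject_id", "tissue", "group",
                           "pm_status", "os_months", "os_event", "age", "stage")]
    rownames(samples) <- NULL

    truth <- list(dep_ids = dep_ids, module_ids = module_ids,
                  true_weights = true_weights, tumor_effects = tumor_effects,
                  pm_effects = pm_effects, beta_hazard = config$beta_hazard,
                  group_labels = stats::setNames(
                    ifelse(pm_status == 1L, "PM", "PM-free"), subj),
                  true_score = score, protein_ids = pid)
    list(expr = expr, peptides = peptides, samples = samples, truth = truth)
  })
}

#' Simulate an external transcriptome cohort concordant with the proteome
#'
#' Builds an ACRG-like external expression cohort on the same identifiers as a
#' simulated proteomic cohort: module genes carry group effects of the same
#' sign as the planted proteomic effects, with magnitudes shrunk by
#' `external_attenuation`; all other genes are pure noise. PM labels are
#' balanced.
#'
#' @param config the [pm_sim_config()] used for the cohort.
#' @param truth the `truth` component returned by [simulate_cohort()].
#' @return list with `expr` (a z-scale [expr_matrix()] tagged `log2z`) and
#'   `samples` (data.frame `sample_id`, `pm_status`).
#' @export
simulate_external_transcriptome <- function(config, truth) {
  if (!inherits(config, "pm_sim_config")) config <- do.call(pm_sim_config, config)
  if (is.null(truth$protein_ids) ||
      !all(truth$module_ids %in% truth$protein_ids)) {
    stop("ground truth does not match the simulated protein universe", call. = FALSE)
  }
  with_seed(child_seed(config$seed, 2L), {
    n <- config$external_n
    pid <- truth$protein_ids
    sid <- sprintf("EXT%03d", seq_len(n))
    pm <- as.integer(seq_len(n) <= ceiling(n / 2))
    v <- matrix(stats::rnorm(length(pid) * n, 0, config$ext_noise_sd),
                nrow = length(pid), dimnames = list(pid, sid))
    if (length(truth$module_ids)) {
      eff <- config$external_attenuation * truth$pm_effects[truth$module_ids]
      v[truth$module_ids, pm == 1L] <- v[truth$module_ids, pm == 1L] + eff
    }
    list(expr = expr_matrix(v, "log2z"),
         samples = data.frame(sample_id = sid, pm_status = pm,
                              stringsAsFactors = FALSE))
  })
}
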