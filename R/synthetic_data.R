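# Synthetic probe-level, behavior and qPCR data with planted ground truth.
#
# The generative model mirrors what RMA-style preprocessing assumes:
# multiplicative (log-additive) true signal with probe-specific affinities,
# Gaussian noise on the log2 scale, plus an additive optical background.
# Single-feature polymorphisms (SFPs) are probe-affinity shifts shared by all
# samples of the affected strain, so they are invisible at the probe-set mean
# after robust summarization but leave a genotype-associated footprint in the
# probe-level residuals.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

#' Simulation configuration for probe-level data
#'
#' Defaults emulate the study design the pipeline targets: 4 strains (2 wild,
#' 2 domesticated) x 2 sexes x 2 replicate pools = 16 arrays, 11 PM/MM probe
#' pairs per probe set, roughly half of the array unexpressed in brain tissue,
#' and planted log2 effects whose magnitudes span fold changes of about 1.9 to
#' 5.6. Fractions are relative to \code{n_probesets}; the planted strain-,
#' domestication- and sex-effect sets and the SFP set are disjoint subsets of
#' the expressed probe sets so that every detector has unambiguous truth.
#'
#' @param n_probesets number of (non-control) probe sets.
#' @param probes_per_probeset PM/MM pairs per probe set.
#' @param strains data.frame with columns \code{strain}, \code{domestication}
#'   defining the panel; default Gaighatta/Nadia wild, SH/TM1 domesticated.
#' @param pools_per_cell biological replicate pools per strain x sex cell.
#' @param pool_size fish pooled per sample.
#' @param fraction_unexpressed fraction of probe sets with no true signal.
#' @param fraction_strain_de,fraction_domestication_de,fraction_sex_de
#'   fractions of probe sets carrying a planted strain-specific,
#'   domestication, or sex effect.
#' @param effect_mean_log2,effect_sd_log2 the absolute planted log2 effect is
#'   drawn from N(effect_mean_log2, effect_sd_log2) truncated below at 0.89
#'   (fold change 1.85); its sign is random.
#' @param biological_strain_sd SD of gene-level biological strain variation
#'   (log2), applied to every expressed probe set on top of any planted
#'   effect. This is what gives real strain panels their across-chip
#'   variability; without it the IQR filter would remove every gene that
#'   carries no planted effect.
#' @param fraction_sfp_probesets fraction of probe sets carrying SFP probes.
#' @param sfp_probes_per_probeset number of affected probes per SFP probe set.
#' @param sfp_affinity_shift_log2 absolute log2 affinity shift of an SFP probe
#'   in the affected strain.
#' @param probe_affinity_sd SD of probe-specific log2 affinities.
#' @param measurement_noise_sd SD of log2-scale measurement noise.
#' @param background_mean,background_sd additive optical background (linear
#'   scale fluorescence units), truncated strictly positive.
#' @param baseline_mean_log2,baseline_sd_log2 distribution of true expressed
#'   log2 abundances.
#' @param n_controls number of control probe sets (ids prefixed
#'   \code{"AFFX-"}); the first emulates a transgenic reporter expressed only
#'   in the TM1 strain.
#' @param seed integer seed.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
sim_config <- function(n_probesets = 2000L,
                       probes_per_probeset = 11L,
                       strains = data.frame(
                         strain = c("Gaighatta", "Nadia", "SH", "TM1"),
                         domestication = c("wild", "wild", "domesticated", "domesticated"),
                         stringsAsFactors = FALSE),
                       pools_per_cell = 2L,
                       pool_size = 4L,
                       fraction_unexpressed = 0.45,
                       fraction_strain_de = 0.10,
                       fraction_domestication_de = 0.05,
                       fraction_sex_de = 0.01,
                       effect_mean_log2 = 1.25,
                       effect_sd_log2 = 0.5,
                       biological_strain_sd = 0.5,
                       fraction_sfp_probesets = 0.05,
                       sfp_probes_per_probeset = 2L,
                       sfp_affinity_shift_log2 = 1.5,
                       probe_affinity_sd = 0.8,
                       measurement_noise_sd = 0.25,
                       background_mean = 100,
                       background_sd = 20,
                       baseline_mean_log2 = 10,
                       baseline_sd_log2 = 1.2,
                       n_controls = 3L,
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(cfg$fraction_unexpressed, cfg$fraction_strain_de,
          cfg$fraction_domestication_de, cfg$fraction_sex_de,
          cfg$fraction_sfp_probesets)
  if (any(fr < 0) || any(fr > 1))
    sa_error("config", "all fractions must lie in [0, 1]")
  n <- cfg$n_probesets
  planted <- round(n * fr)
  if (sum(planted) > n)
    sa_error("config", sprintf(
      "infeasible fractions: %d unexpressed + planted sets exceed %d probe sets",
      planted[1L], n))
  if (cfg$probes_per_probeset < 3L)
    sa_error("config", "probes_per_probeset must be >= 3")
  sds <- c(cfg$effect_sd_log2, cfg$probe_affinity_sd, cfg$measurement_noise_sd,
           cfg$background_sd, cfg$baseline_sd_log2, cfg$biological_strain_sd)
  if (any(sds < 0)) sa_error("config", "standard deviations must be >= 0")
  if (!all(cfg$strains$domestication %in% c("wild", "domesticated")))
    sa_error("config", "strain panel domestication must be wild/domesticated")
  structure(cfg, class = "SimulationConfig")
}

sample_sheet_from_config <- function(config) {
  grid <- expand.grid(pool = seq_len(config$pools_per_cell),
                      sex = c("F", "M"),
                      strain = config$strains$strain,
                      stringsAsFactors = FALSE)
  dom <- config$strains$domestication[match(grid$strain, config$strains$strain)]
  data.frame(sample_id = sprintf("%s_%s_%d", grid$strain, grid$sex, grid$pool),
             strain = grid$strain, domestication = dom, sex = grid$sex,
             pool_size = config$pool_size, stringsAsFactors = FALSE)
}

#' Generate a probe-level dataset with planted ground truth
#'
#' Simulates PM and MM intensities under the model
#' \deqn{PM_{ji} = 2^{\mu_{g(j),s(i)} + \phi_j + \delta_{j,s(i)} + \epsilon_{ji}} + b_{ji}}
#' where \eqn{\mu_{gs}} is the true log2 abundance of probe set \eqn{g} in the
#' strain/sex group of sample \eqn{i} (zero for unexpressed probe sets),
#' \eqn{\phi_j} a probe affinity, \eqn{\delta_{j,s}} the SFP affinity shift of
#' probe \eqn{j} in strain \eqn{s} (zero off the planted probes), and
#' \eqn{b} a truncated-normal optical background. MM probes carry affinity and
#' background but no true-signal term (cross-hybridization only), which is what
#' makes the PM-MM discrimination score informative for detection calls.
#'
#' @param config a [sim_config()].
#' @return list with elements \code{dataset} (a \code{ProbeLevelDataset}) and
#'   \code{truth} (list: \code{probesets} and \code{probes} data.frames plus
#'   the config), sufficient to score every downstream detector.
#' @export
generate_probe_level_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    samples <- sample_sheet_from_config(config)
    n_samp <- nrow(samples)
    n <- config$n_probesets
    strain_names <- config$strains$strain
    dom_strains <- strain_names[config$strains$domestication == "domesticated"]

    ps_ids <- sprintf("ps%05d", seq_len(n))
    n_unexpr <- round(n * config$fraction_unexpressed)
    n_strain <- round(n * config$fraction_strain_de)
    n_dom <- round(n * config$fraction_domestication_de)
    n_sex <- round(n * config$fraction_sex_de)
    n_sfp <- round(n * config$fraction_sfp_probesets)

    idx <- sample.int(n)             # random disjoint assignment
    unexpr_idx <- idx[seq_len(n_unexpr)]
    pool <- idx[-seq_len(n_unexpr)]  # expressed probe sets
    strain_idx <- pool[seq_len(n_strain)]
    dom_idx <- pool[n_strain + seq_len(n_dom)]
    sex_idx <- pool[n_strain + n_dom + seq_len(n_sex)]
    sfp_idx <- pool[n_strain + n_dom + n_sex + seq_len(n_sfp)]

    expressed <- !(seq_len(n) %in% unexpr_idx)
    baseline <- ifelse(expressed,
                       stats::rnorm(n, config$baseline_mean_log2,
                                    config$baseline_sd_log2), 0)

    draw_effect <- function(k)
      pmax(stats::rnorm(k, config$effect_mean_log2, config$effect_sd_log2), 0.89) *
        sample(c(-1, 1), k, replace = TRUE)

    wild_strains <- strain_names[config$strains$domestication == "wild"]
    strain_effects <- matrix(0, n, length(strain_names),
                             dimnames = list(ps_ids, strain_names))
    # strain-specific effects on a mixed (one wild + one domesticated) pair so
    # the planted among-strain signal is orthogonal to the domestication
    # contrast
    if (n_strain > 0L) {
      hit_wild <- sample(wild_strains, n_strain, replace = TRUE)
      hit_dom <- sample(dom_strains, n_strain, replace = TRUE)
      eff <- draw_effect(n_strain)
      strain_effects[cbind(strain_idx, match(hit_wild, strain_names))] <- eff
      strain_effects[cbind(strain_idx, match(hit_dom, strain_names))] <- eff
    }
    # biological strain variation on expressed probe sets without planted
    # effects (for planted genes the effect IS the strain variation, so the
    # recorded truth stays exact)
    unplanted <- expressed & !(seq_len(n) %in% c(strain_idx, dom_idx, sex_idx))
    bio <- matrix(stats::rnorm(n * length(strain_names), 0,
                               config$biological_strain_sd),
                  n, length(strain_names),
                  dimnames = list(ps_ids, strain_names)) * unplanted
    dom_effect <- numeric(n)         # positive = higher in domesticated
    if (n_dom > 0L) {
      dom_effect[dom_idx] <- draw_effect(n_dom)
      strain_effects[dom_idx, dom_strains] <-
        strain_effects[dom_idx, dom_strains] + dom_effect[dom_idx]
    }
    sex_effect <- numeric(n)         # applied to males
    if (n_sex > 0L) sex_effect[sex_idx] <- draw_effect(n_sex)

    # control probe sets: first one emulates a transgenic reporter in TM1
    ctl_ids <- character(0)
    if (config$n_controls > 0L) {
      ctl_ids <- sprintf("AFFX-ctrl-%02d_at", seq_len(config$n_controls))
      if (config$n_controls >= 1L) ctl_ids[1L] <- "AFFX-reporter-1_at"
    }
    all_ids <- c(ps_ids, ctl_ids)
    n_all <- length(all_ids)
    ctl_baseline <- rep(config$baseline_mean_log2, length(ctl_ids))
    ctl_strain_eff <- matrix(0, length(ctl_ids), length(strain_names),
                             dimnames = list(ctl_ids, strain_names))
    if (length(ctl_ids) >= 1L && "TM1" %in% strain_names) {
      ctl_baseline[1L] <- 4
      ctl_strain_eff[1L, "TM1"] <- 5   # reporter expressed only in TM1
    }

    probesets <- data.frame(
      probeset_id = all_ids,
      is_control = c(rep(FALSE, n), rep(TRUE, length(ctl_ids))),
      expressed = c(expressed, rep(TRUE, length(ctl_ids))),
      baseline_log2 = c(baseline, ctl_baseline),
      de_strain = c(seq_len(n) %in% c(strain_idx, dom_idx), rep(FALSE, length(ctl_ids))),
      de_domestication = c(seq_len(n) %in% dom_idx, rep(FALSE, length(ctl_ids))),
      de_sex = c(seq_len(n) %in% sex_idx, rep(FALSE, length(ctl_ids))),
      dom_effect_log2 = c(dom_effect, rep(0, length(ctl_ids))),
      sex_effect_log2 = c(sex_effect, rep(0, length(ctl_ids))),
      sfp = c(seq_len(n) %in% sfp_idx, rep(FALSE, length(ctl_ids))),
      stringsAsFactors = FALSE)
    eff_all <- rbind(strain_effects, ctl_strain_eff)
    colnames(eff_all) <- paste0("effect_", strain_names)
    bio_all <- rbind(bio, ctl_strain_eff * 0)
    colnames(bio_all) <- paste0("bio_", strain_names)
    probesets <- cbind(probesets, as.data.frame(eff_all), as.data.frame(bio_all))

    # per-probe quantities
    npp <- config$probes_per_probeset
    probe_probeset <- rep(all_ids, each = npp)
    probe_ids <- paste0(probe_probeset, ":", rep(seq_len(npp), n_all))
    affinity <- stats::rnorm(n_all * npp, 0, config$probe_affinity_sd)
    sfp_flag <- logical(n_all * npp)
    sfp_strain <- rep(NA_character_, n_all * npp)
    sfp_shift <- numeric(n_all * npp)
    if (n_sfp > 0L) {
      for (g in sfp_idx) {
        rows <- (g - 1L) * npp + sample.int(npp, config$sfp_probes_per_probeset)
        st <- sample(strain_names, 1L)
        sfp_flag[rows] <- TRUE
        sfp_strain[rows] <- st
        sfp_shift[rows] <- config$sfp_affinity_shift_log2 *
          sample(c(-1, 1), 1L)
      }
    }
    probes <- data.frame(probe_id = probe_ids, probeset_id = probe_probeset,
                         affinity = affinity, sfp = sfp_flag,
                         sfp_strain = sfp_strain, sfp_shift = sfp_shift,
                         stringsAsFactors = FALSE)

    # true log2 abundance per probe set x sample
    base_all <- probesets$baseline_log2
    expr_all <- probesets$expressed
    mu <- matrix(0, n_all, n_samp, dimnames = list(all_ids, samples$sample_id))
    strain_of <- samples$strain
    male <- samples$sex == "M"
    eff_mat <- as.matrix(probesets[, paste0("effect_", strain_names)]) +
      as.matrix(probesets[, paste0("bio_", strain_names)])
    for (i in seq_len(n_samp)) {
      mu[, i] <- ifelse(expr_all,
                        base_all + eff_mat[, match(strain_of[i], strain_names)] +
                          probesets$sex_effect_log2 * male[i],
                        0)
    }

    P <- n_all * npp
    mu_probe <- mu[probe_probeset, , drop = FALSE]
    shift_mat <- matrix(0, P, n_samp)
    has_shift <- which(sfp_flag)
    if (length(has_shift) > 0L) {
      for (j in has_shift)
        shift_mat[j, strain_of == sfp_strain[j]] <- sfp_shift[j]
    }
    rbg <- function() {
      b <- matrix(stats::rnorm(P * n_samp, config$background_mean,
                               config$background_sd), P, n_samp)
      pmax(b, 1)
    }
    eps <- matrix(stats::rnorm(P * n_samp, 0, config$measurement_noise_sd), P, n_samp)
    pm <- 2^(mu_probe + affinity + shift_mat + eps) + rbg()
    eps_mm <- matrix(stats::rnorm(P * n_samp, 0, config$measurement_noise_sd), P, n_samp)
    mm <- 2^(affinity + eps_mm) + rbg()
    dimnames(pm) <- dimnames(mm) <- list(probe_ids, samples$sample_id)

    dataset <- probe_level_dataset(pm, mm, samples)
    truth <- list(probesets = probesets, probes = probes, config = config)
    list(dataset = dataset, truth = truth)
  })
}

#' Generate behavior assay observations with planted strain effects
#'
#' Emulates a place-preference assay: each fish is observed over
#' \code{n_periods} periods with \code{recordings_per_period} recordings per
#' period; each recording yields a vertical zone (integer 1 = surface to
#' 6 = bottom) and a binary flag for being within one body length of the front
#' of the tank. Fish-level repeatability is controlled through the ratio of
#' between-fish to total latent variance (\code{icc}); the default 0.5 sits in
#' the 0.4-0.6 range reported for this assay.
#'
#' @param n_fish_per_strain fish per strain (sexes balanced).
#' @param n_periods observation periods per fish.
#' @param recordings_per_period recordings per period.
#' @param strain_effects data.frame with columns \code{strain},
#'   \code{domestication}, \code{depth_mean} (latent zone mean, in [1, 6]) and
#'   \code{front_prob} (probability in [0, 1]). Defaults place wild strains
#'   deeper and less front-oriented than domesticated strains.
#' @param icc target intraclass correlation of the latent depth (between-fish
#'   variance / total latent variance).
#' @param within_sd SD of the recording-level latent depth noise (zones).
#' @param front_logit_sd SD of the per-fish front-preference deviation on the
#'   logit scale.
#' @param seed integer seed.
#' @return list with \code{observations} (long data.frame: fish_id, strain,
#'   domestication, sex, period, recording, vertical_zone, front_flag) and
#'   \code{truth} (per-fish latent means and preferences).
#' @export
generate_behavior_data <- function(n_fish_per_strain = 16L,
                                   n_periods = 30L,
                                   recordings_per_period = 3L,
                                   strain_effects = data.frame(
                                     strain = c("Gaighatta", "Nadia", "SH", "TM1"),
                                     domestication = c("wild", "wild",
                                                       "domesticated", "domesticated"),
                                     depth_mean = c(4.9, 4.6, 2.4, 2.6),
                                     front_prob = c(0.10, 0.12, 0.55, 0.50),
                                     stringsAsFactors = FALSE),
                                   icc = 0.5,
                                   within_sd = 1.0,
                                   front_logit_sd = 0.75,
                                   seed = 1L) {
  if (n_periods < 1L) sa_error("config", "n_periods must be >= 1")
  if (any(strain_effects$depth_mean < 1) || any(strain_effects$depth_mean > 6))
    sa_error("config", "latent depth means must lie in [1, 6]")
  if (any(strain_effects$front_prob < 0) || any(strain_effects$front_prob > 1))
    sa_error("config", "front probabilities must lie in [0, 1]")
  if (icc < 0 || icc >= 1) sa_error("config", "icc must lie in [0, 1)")
  with_seed(seed, {
    between_sd <- within_sd * sqrt(icc / (1 - icc))
    fish <- do.call(rbind, lapply(seq_len(nrow(strain_effects)), function(k) {
      st <- strain_effects[k, ]
      data.frame(fish_id = sprintf("%s_f%02d", st$strain, seq_len(n_fish_per_strain)),
                 strain = st$strain, domestication = st$domestication,
                 sex = rep_len(c("F", "M"), n_fish_per_strain),
                 latent_depth = pmin(pmax(
                   st$depth_mean + stats::rnorm(n_fish_per_strain, 0, between_sd),
                   1), 6),
                 front_p = stats::plogis(stats::qlogis(st$front_prob) +
                   stats::rnorm(n_fish_per_strain, 0, front_logit_sd)),
                 stringsAsFactors = FALSE)
    }))
    n_rec <- n_periods * recordings_per_period
    obs <- fish[rep(seq_len(nrow(fish)), each = n_rec),
                c("fish_id", "strain", "domestication", "sex")]
    obs$period <- rep(rep(seq_len(n_periods), each = recordings_per_period),
                      times = nrow(fish))
    obs$recording <- rep(seq_len(recordings_per_period),
                         times = nrow(fish) * n_periods)
    latent <- rep(fish$latent_depth, each = n_rec)
    obs$vertical_zone <- pmin(pmax(round(
      latent + stats::rnorm(nrow(obs), 0, within_sd)), 1L), 6L)
    obs$front_flag <- stats::rbinom(nrow(obs), 1L, rep(fish$front_p, each = n_rec))
    rownames(obs) <- NULL
    list(observations = obs,
         truth = list(fish = fish, strain_effects = strain_effects,
                      icc = icc, within_sd = within_sd))
  })
}

#' Generate qRT-PCR C_T data with a reference-gene covariate
#'
#' Emulates the validation design: one target and one reference gene measured
#' on each biological pool. The reference C_T varies around
#' \code{reference_mean_ct}; the target C_T tracks it with slope \code{beta}
#' (default 1, the usual assumption behind delta-C_T normalization) plus a
#' strain mean and independent noise.
#'
#' @param strain_means_ct named numeric: true target C_T per strain (at the
#'   mean reference C_T).
#' @param reference_mean_ct mean reference-gene C_T.
#' @param noise_sd SD of both the reference draw and the target residual.
#' @param beta slope of target on reference C_T.
#' @param sex_effect_ct additive C_T shift for males (default 0).
#' @param pools_per_cell replicate pools per strain x sex.
#' @param domestication named character mapping strain -> class (defaults to
#'   the standard panel where names match).
#' @param seed integer seed.
#' @return list with \code{qpcr} (data.frame: sample_id, strain, sex,
#'   ct_target, ct_reference) and \code{truth}.
#' @export
generate_qpcr_data <- function(strain_means_ct = c(Gaighatta = 24, Nadia = 24.5,
                                                   SH = 26, TM1 = 25.5),
                               reference_mean_ct = 20,
                               noise_sd = 0.2,
                               beta = 1,
                               sex_effect_ct = 0,
                               pools_per_cell = 2L,
                               domestication = NULL,
                               seed = 1L) {
  if (noise_sd < 0) sa_error("config", "noise_sd must be >= 0")
  strains <- names(strain_means_ct)
  if (is.null(strains)) sa_error("config", "strain_means_ct must be named by strain")
  if (is.null(domestication)) {
    default <- c(Gaighatta = "wild", Nadia = "wild",
                 SH = "domesticated", TM1 = "domesticated")
    domestication <- ifelse(strains %in% names(default),
                            default[strains], "wild")
    names(domestication) <- strains
  }
  with_seed(seed, {
    grid <- expand.grid(pool = seq_len(pools_per_cell), sex = c("F", "M"),
                        strain = strains, stringsAsFactors = FALSE)
    n <- nrow(grid)
    ct_ref <- stats::rnorm(n, reference_mean_ct, noise_sd)
    ct_tgt <- strain_means_ct[grid$strain] +
      sex_effect_ct * (grid$sex == "M") +
      beta * (ct_ref - reference_mean_ct) +
      stats::rnorm(n, 0, noise_sd)
    qpcr <- data.frame(
      sample_id = sprintf("%s_%s_%d", grid$strain, grid$sex, grid$pool),
      strain = grid$strain,
      domestication = unname(domestication[grid$strain]),
      sex = grid$sex,
      ct_target = unname(ct_tgt), ct_reference = ct_ref,
      stringsAsFactors = FALSE)
    list(qpcr = qpcr,
         truth = list(strain_means_ct = strain_means_ct, beta = beta,
                      reference_mean_ct = reference_mean_ct,
                      sex_effect_ct = sex_effect_ct, noise_sd = noise_sd))
  })
}
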