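# End-to-end orchestration: preprocessing, filters, SFP removal, moderated
# differential expression, fold changes, range-overlap filter, enrichment,
# and the count ledger tracking how many probe sets survive each stage.

#' Run the full strain-comparison pipeline
#'
#' Executes, in order: RMA-style preprocessing, detection calls, the
#' expression and IQR filters (defining the expressed set), SFP flagging and
#' removal, control probe-set exclusion, gene-wise moderated linear models
#' with the among-strain F test, the wild-vs-domesticated contrast with the
#' range-overlap filter, the sex contrast from the factorial model, fold
#' changes, and (when an annotation is supplied) EASE overrepresentation of
#' the among-strain list against the expressed background. All counts in the
#' ledger refer to non-control probe sets. Fully deterministic given the seed.
#'
#' @param dataset a \code{ProbeLevelDataset}.
#' @param annotation optional \code{AnnotationTable} for enrichment.
#' @param tau,p_present,p_absent detection-call parameters.
#' @param absent_percentile quantile for the expression threshold.
#' @param min_iqr IQR filter threshold.
#' @param sfp_alpha,n_permutations,s0 SFP screen parameters.
#' @param fdr BH threshold for all differential-expression lists.
#' @param fold_threshold fold-change threshold for the "2-fold" counts.
#' @param max_overlap range-overlap tolerance for domestication candidates.
#' @param control_exclusion \code{"pre_model"} (default) removes control probe
#'   sets before model fitting so ledger counts are control-free by
#'   construction; \code{"post_hoc"} fits them and drops them from the final
#'   lists (the ordering used when validating against external data).
#' @param seed integer seed for the SFP permutations.
#' @param output_dir optional directory; when given, every stage table, the
#'   ledger (JSON) and a log are written there.
#' @return list of class \code{PipelineResult}: \code{ledger}, \code{expr}
#'   (analyzed expression matrix), \code{expr_expressed}, \code{calls},
#'   \code{threshold}, \code{sfp}, \code{de_strain}, \code{fc_strain},
#'   \code{de_domestication}, \code{overlap}, \code{de_sex},
#'   \code{enrichment}, \code{expressed_ids}, \code{analyzed_ids},
#'   \code{params}, \code{log}.
#' @export
run_pipeline <- function(dataset, annotation = NULL,
                         tau = 0.015, p_present = 0.04, p_absent = 0.04,
                         absent_percentile = 0.99, min_iqr = 0.5,
                         sfp_alpha = 0.01, n_permutations = 1000L, s0 = "auto",
                         fdr = 0.05, fold_threshold = 2, max_overlap = 1L,
                         control_exclusion = c("pre_model", "post_hoc"),
                         seed = 1L, output_dir = NULL) {
  stopifnot(inherits(dataset, "ProbeLevelDataset"))
  control_exclusion <- match.arg(control_exclusion)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  samples <- dataset$samples
  is_control <- dataset$control_flags
  noncontrol <- names(is_control)[!is_control]
  say("input: %d probe sets (%d controls), %d samples",
      length(is_control), sum(is_control), ncol(dataset$pm))

  pre <- stage("preprocess", rma_preprocess(dataset))
  calls <- stage("detection_calls",
                 detection_calls(dataset, tau = tau, p_present = p_present,
                                 p_absent = p_absent))
  ef <- stage("expression_filter",
              expression_threshold_filter(pre$expr, calls,
                                          percentile = absent_percentile))
  say("expression filter: threshold %.4f, removed %d probe sets",
      ef$threshold[1L], length(ef$removed))
  iq <- stage("iqr_filter", iqr_filter(ef$expr, min_iqr = min_iqr))
  say("IQR filter: removed %d probe sets", length(iq$removed))
  expr_expressed <- iq$expr
  expressed_ids <- intersect(rownames(expr_expressed), noncontrol)

  probe_keep <- dataset$probe_map$probeset_id %in% rownames(expr_expressed)
  probes_sub <- pre$probes_log2[probe_keep, , drop = FALSE]
  map_sub <- dataset$probe_map[probe_keep, , drop = FALSE]
  resid <- stage("sfp_residuals",
                 compute_probe_residuals(probes_sub, expr_expressed, map_sub))
  sam <- stage("sfp_sam",
               sam_multiclass(resid, samples$strain,
                              n_permutations = n_permutations,
                              seed = seed, s0 = s0))
  sfp <- stage("sfp_flag", flag_sfp_probesets(sam, map_sub, alpha = sfp_alpha))
  flagged_ids <- sfp$probesets$probeset_id[sfp$probesets$flagged]
  flagged_noncontrol <- intersect(flagged_ids, expressed_ids)
  say("SFP screen: %d probe sets flagged at q < %.3g", length(flagged_ids),
      sfp_alpha)

  analyzed_ids <- setdiff(expressed_ids, flagged_noncontrol)
  model_ids <- if (control_exclusion == "pre_model") analyzed_ids
               else setdiff(rownames(expr_expressed), flagged_ids)
  expr_model <- expr_expressed[model_ids, , drop = FALSE]

  ds_strain <- strain_design(samples)
  mfit_strain <- stage("linear_models",
                       moderate_variances(fit_gene_linear_models(expr_model,
                                                                 ds_strain)))
  de_strain <- stage("contrast_among_strain",
                     test_contrasts(mfit_strain, "among_strain"))
  de_dom <- stage("contrast_wild_vs_domesticated",
                  test_contrasts(mfit_strain, "wild_vs_domesticated"))
  ds_fact <- factorial_design(samples)
  mfit_fact <- stage("factorial_models",
                     moderate_variances(fit_gene_linear_models(expr_model,
                                                               ds_fact)))
  de_sex <- stage("contrast_sex", test_contrasts(mfit_fact, "sex"))
  if (control_exclusion == "post_hoc") {
    de_strain <- de_strain[de_strain$probeset_id %in% analyzed_ids, ]
    de_dom <- de_dom[de_dom$probeset_id %in% analyzed_ids, ]
    de_sex <- de_sex[de_sex$probeset_id %in% analyzed_ids, ]
  }

  fc_strain <- stage("fold_changes",
                     fold_changes(expr_model[de_strain$probeset_id, ,
                                             drop = FALSE], samples$strain))
  de_strain$max_pairwise_fc <- fc_strain$fold_change[
    match(de_strain$probeset_id, fc_strain$probeset_id)]

  strain_hits <- de_strain$probeset_id[de_strain$adj_p < fdr]
  dom_hits <- de_dom$probeset_id[de_dom$adj_p < fdr]
  wild_s <- samples$sample_id[samples$domestication == "wild"]
  dom_s <- samples$sample_id[samples$domestication == "domesticated"]
  overlap <- stage("range_overlap",
                   if (length(dom_hits) > 0L)
                     range_overlap_filter(expr_model, wild_s, dom_s,
                                          candidates = dom_hits,
                                          max_overlap = max_overlap)
                   else data.frame(probeset_id = character(0),
                                   overlap = integer(0), retained = logical(0)))
  dom_final <- overlap$probeset_id[overlap$retained]
  sex_hits <- de_sex$probeset_id[de_sex$adj_p < fdr]

  fc_of <- function(ids, tab) {
    if (length(ids) == 0L) return(character(0))
    fc <- tab$fold_change[match(ids, tab$probeset_id)]
    ids[!is.na(fc) & fc >= fold_threshold]
  }
  ledger <- list(
    n_probesets_total = length(noncontrol),
    n_expressed = length(expressed_ids),
    n_sfp_flagged = length(flagged_noncontrol),
    n_analyzed = length(analyzed_ids),
    n_de_strain = length(strain_hits),
    n_de_strain_2fold = length(fc_of(strain_hits, fc_strain)),
    n_de_dom_initial = length(dom_hits),
    n_de_dom_final = length(dom_final),
    n_de_dom_2fold = length(fc_of(dom_final, de_dom)),
    n_de_sex = length(sex_hits))
  say("ledger: %s", paste(sprintf("%s=%d", names(ledger), unlist(ledger)),
                          collapse = " "))

  enr <- NULL
  if (!is.null(annotation)) {
    enr <- stage("enrichment",
                 run_enrichment(strain_hits, expressed_ids, annotation))
    say("enrichment: %d categories tested, %d flagged", nrow(enr),
        sum(enr$flagged))
  }

  params <- list(tau = tau, p_present = p_present, p_absent = p_absent,
                 absent_percentile = absent_percentile, min_iqr = min_iqr,
                 sfp_alpha = sfp_alpha, n_permutations = n_permutations,
                 s0 = s0, fdr = fdr, fold_threshold = fold_threshold,
                 max_overlap = max_overlap,
                 control_exclusion = control_exclusion, seed = seed)
  result <- structure(list(
    ledger = ledger, expr = expr_model, expr_expressed = expr_expressed,
    calls = calls, threshold = ef$threshold, sfp = sfp,
    de_strain = de_strain, fc_strain = fc_strain,
    de_domestication = de_dom, overlap = overlap, de_sex = de_sex,
    enrichment = enr, expressed_ids = expressed_ids,
    analyzed_ids = analyzed_ids, strain_hits = strain_hits,
    dom_hits_initial = dom_hits, dom_hits_final = dom_final,
    sex_hits = sex_hits, params = params, log = log_lines),
    class = "PipelineResult")
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("strainarray pipeline result\n")
  for (nm in names(x$ledger)) cat(sprintf("  %-20s %d\n", nm, x$ledger[[nm]]))
  invisible(x)
}

#' Write all pipeline stage outputs to a directory
#'
#' Emits \code{expr.tsv}, \code{calls.tsv}, \code{sfp.tsv},
#' \code{de_strain.tsv}, \code{de_domestication.tsv}, \code{de_sex.tsv},
#' \code{enrich.tsv} (if computed), \code{ledger.json}, \code{params.yaml} and
#' \code{log.txt}.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_df <- data.frame(probeset_id = rownames(result$expr),
                        as.data.frame(result$expr, check.names = FALSE),
                        check.names = FALSE)
  write_result_table(expr_df, file.path(dir, "expr.tsv"), p_col = NA)
  calls_df <- data.frame(probeset_id = rownames(result$calls$call),
                         as.data.frame(result$calls$call, check.names = FALSE),
                         check.names = FALSE)
  write_result_table(calls_df, file.path(dir, "calls.tsv"), p_col = NA)
  write_result_table(result$sfp$probesets, file.path(dir, "sfp.tsv"), p_col = NA)
  write_result_table(result$de_strain, file.path(dir, "de_strain.tsv"))
  write_result_table(result$de_domestication,
                     file.path(dir, "de_domestication.tsv"))
  write_result_table(result$de_sex, file.path(dir, "de_sex.tsv"))
  if (!is.null(result$enrichment))
    write_result_table(result$enrichment, file.path(dir, "enrich.tsv"))
  jsonlite::write_json(result$ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE)
  yaml::write_yaml(result$params, file.path(dir, "params.yaml"))
  writeLines(result$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' Run the pipeline from a YAML configuration
#'
#' The configuration either names input files
#' (\code{inputs: pm/mm/samples[/annotation]}) or requests simulation
#' (\code{simulate:} with [sim_config()] fields); \code{params:} carries any
#' [run_pipeline()] arguments and \code{out:} the output directory. The
#' parameters are echoed into the output directory for provenance.
#'
#' @param config path to a YAML file or an equivalent list.
#' @return the [run_pipeline()] result.
#' @export
run_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$inputs)) {
    dataset <- load_probe_level_dataset(config$inputs$pm, config$inputs$mm,
                                        config$inputs$samples)
    annotation <- if (!is.null(config$inputs$annotation))
      load_annotation_table(config$inputs$annotation) else NULL
  } else if (!is.null(config$simulate)) {
    sim <- generate_probe_level_dataset(do.call(sim_config, config$simulate))
    dataset <- sim$dataset
    annotation <- NULL
  } else {
    sa_error("config", "configuration needs an 'inputs' or 'simulate' section")
  }
  args <- c(list(dataset = dataset, annotation = annotation,
                 output_dir = config$out), config$params)
  do.call(run_pipeline, args)
}
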