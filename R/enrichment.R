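# Category overrepresentation with the EASE score: a one-tailed Fisher exact
# (hypergeometric upper tail) probability computed after removing one gene
# from the list-and-category cell, which penalizes categories supported by a
# single gene and makes the score conservative relative to plain Fisher.

#' EASE score for one category
#'
#' With \code{list_hits} category members among \code{list_size} list genes
#' drawn from a background of \code{bg_size} genes containing \code{bg_hits}
#' category members, the EASE score is the hypergeometric upper-tail
#' probability of observing at least \code{list_hits - 1} members (the
#' jackknife penalty). A list with no category member scores 1.
#'
#' @param list_hits,list_size,bg_hits,bg_size 2x2 table margins.
#' @return p-value in (0, 1].
#' @export
ease_score <- function(list_hits, list_size, bg_hits, bg_size) {
  check_counts(list_hits, list_size, bg_hits, bg_size)
  if (list_hits == 0L) return(1)
  stats::phyper(list_hits - 2L, bg_hits, bg_size - bg_hits, list_size,
                lower.tail = FALSE)
}

#' Plain one-tailed Fisher exact p (no jackknife), for comparison
#' @inheritParams ease_score
#' @return p-value in (0, 1].
#' @export
fisher_upper_p <- function(list_hits, list_size, bg_hits, bg_size) {
  check_counts(list_hits, list_size, bg_hits, bg_size)
  stats::phyper(list_hits - 1L, bg_hits, bg_size - bg_hits, list_size,
                lower.tail = FALSE)
}

check_counts <- function(list_hits, list_size, bg_hits, bg_size) {
  if (any(c(list_hits, list_size, bg_hits, bg_size) < 0) ||
      list_hits > list_size || list_size > bg_size || list_hits > bg_hits ||
      bg_hits > bg_size)
    sa_error("value", sprintf(
      "inconsistent counts: list_hits=%d list_size=%d bg_hits=%d bg_size=%d",
      list_hits, list_size, bg_hits, bg_size))
  invisible(TRUE)
}

#' Category overrepresentation in a gene list
#'
#' Scores every annotation category with at least one list hit against the
#' expressed background using [ease_score()], reports BH-adjusted p-values
#' alongside, and flags categories with EASE p below \code{alpha}. The
#' background must be the set of expressed genes (not the whole array); a list
#' gene absent from the background is an error, guarding against background
#' misuse.
#'
#' @param gene_list character vector of probe-set ids (subset of
#'   \code{background}).
#' @param background character vector of expressed probe-set ids.
#' @param annotation an \code{AnnotationTable} from [load_annotation_table()]
#'   (or a list with the same structure).
#' @param alpha EASE-score threshold for flagging (default 0.05).
#' @return data.frame: category_id, label, list_hits, list_size, bg_hits,
#'   bg_size, p (EASE), adj_p, flagged; ordered by p.
#' @export
run_enrichment <- function(gene_list, background, annotation, alpha = 0.05) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  outside <- setdiff(gene_list, background)
  if (length(outside) > 0L)
    sa_error("value", paste("gene(s) in list but not in background:",
                            paste(utils::head(outside, 5L), collapse = ", ")))
  memb <- annotation$membership
  memb <- memb[memb$probeset_id %in% background, , drop = FALSE]
  if (nrow(memb) == 0L)
    return(data.frame(category_id = character(0), label = character(0),
                      list_hits = integer(0), list_size = integer(0),
                      bg_hits = integer(0), bg_size = integer(0),
                      p = numeric(0), adj_p = numeric(0), flagged = logical(0)))
  bg_hits <- table(memb$category_id)
  in_list <- memb$probeset_id %in% gene_list
  list_hits <- table(memb$category_id[in_list])
  cats <- names(list_hits)[list_hits > 0L]
  L <- length(gene_list); B <- length(background)
  p <- vapply(cats, function(cg)
    ease_score(as.integer(list_hits[cg]), L, as.integer(bg_hits[cg]), B), 1.0)
  res <- data.frame(
    category_id = cats,
    label = unname(annotation$labels[cats]),
    list_hits = as.integer(list_hits[cats]),
    list_size = L,
    bg_hits = as.integer(bg_hits[cats]),
    bg_size = B,
    p = unname(p),
    stringsAsFactors = FALSE)
  res$adj_p <- bh_adjust(res$p)
  res$flagged <- res$p < alpha
  res[order(res$p, res$category_id), , drop = FALSE]
}
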