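# Error statistics for one realized-vs-truth comparison. The edit distance
# is the unit-cost Levenshtein distance; SNPs and indel events come from an
# affine-gap global alignment, which keeps a contiguous indel as a single
# event instead of the arbitrary fragmentation a unit-cost traceback can
# produce.
.edit_stats <- function(realized, truth) {
  pa <- Biostrings::pairwiseAlignment(
    realized, truth, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 1)
  widths <- c(unlist(Biostrings::width(Biostrings::indel(
                Biostrings::pattern(pa)))),
              unlist(Biostrings::width(Biostrings::indel(
                Biostrings::subject(pa)))))
  list(snps = Biostrings::nmismatch(pa),
       indels_le5 = sum(widths <= 5L),
       indels_gt5 = sum(widths > 5L),
       edit_dist = as.integer(utils::adist(realized, truth)))
}

#' Evaluate closures against the simulation truth
#'
#' For every gap in the truth registry, the realized sequence of its
#' (enlarged) interval is extracted from the final assembly and globally
#' aligned to the true sequence (including the flank bases that edge
#' trimming converted to N). The reported edit distance is the unit-cost
#' Levenshtein distance; errors are classified from an affine-gap global
#' alignment into SNPs (mismatch columns) and indel events — contiguous
#' inserted or deleted blocks — split at 5 bp. Structural misjoins are not
#' assessed; they require whole-assembly alignment, not per-gap comparison.
#' Error counts are reported for closed gaps; `PARTIAL` and `OPEN` gaps
#' carry zero counts.
#'
#' @param result A [fill_scaffold_gaps()] result.
#' @param registry Truth registry from [make_gapped_scaffolds()].
#' @return An object of class `"closure_eval"`: list with `gaps` (per-gap
#'   data frame: `gap_id`, `status` in PERFECT / CLOSED_WITH_ERRORS /
#'   PARTIAL / OPEN, `snps`, `indels_le5`, `indels_gt5`, `edit_dist`) and
#'   `totals`.
#' @export
evaluate_closure <- function(result, registry) {
  reg <- registry$gaps
  tab <- result$gaps
  if (nrow(reg) == 0L) {
    per <- data.frame(gap_id = character(), status = character(),
                      snps = integer(), indels_le5 = integer(),
                      indels_gt5 = integer(), edit_dist = integer())
    return(structure(list(gaps = per, totals = .eval_totals(per)),
                     class = "closure_eval"))
  }
  if (!all(reg$scaffold_id %in% names(result$assembly))) {
    stop("registry scaffold ids do not match the assembly")
  }
  rows <- match(paste(reg$scaffold_id, reg$scaf_start, reg$scaf_end),
                paste(tab$scaffold_id, tab$orig_start, tab$orig_end))
  if (anyNA(rows)) {
    stop("registry gaps do not match the pipeline's gap table")
  }
  per <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    ri <- rows[i]
    truth <- substr(registry$reference,
                    reg$ref_start[i] - tab$tl[ri],
                    reg$ref_end[i] + tab$tr[ri])
    realized <- substr(result$assembly[[reg$scaffold_id[i]]],
                       tab$cur_start[ri], tab$cur_end[ri])
    if (tab$status[ri] != "CLOSED") {
      per[[i]] <- data.frame(gap_id = tab$gap_id[ri],
                             status = tab$status[ri], snps = 0L,
                             indels_le5 = 0L, indels_gt5 = 0L,
                             edit_dist = 0L)
    } else if (identical(realized, truth)) {
      per[[i]] <- data.frame(gap_id = tab$gap_id[ri], status = "PERFECT",
                             snps = 0L, indels_le5 = 0L, indels_gt5 = 0L,
                             edit_dist = 0L)
    } else {
      cls <- .edit_stats(realized, truth)
      per[[i]] <- data.frame(gap_id = tab$gap_id[ri],
                             status = "CLOSED_WITH_ERRORS",
                             snps = cls$snps, indels_le5 = cls$indels_le5,
                             indels_gt5 = cls$indels_gt5,
                             edit_dist = cls$edit_dist)
    }
  }
  per <- do.call(rbind, per)
  structure(list(gaps = per, totals = .eval_totals(per)),
            class = "closure_eval")
}

.eval_totals <- function(per) {
  list(gaps = nrow(per),
       closed = sum(per$status %in% c("PERFECT", "CLOSED_WITH_ERRORS")),
       perfect = sum(per$status == "PERFECT"),
       partial = sum(per$status == "PARTIAL"),
       open = sum(per$status == "OPEN"),
       snps = sum(per$snps),
       indels_le5 = sum(per$indels_le5),
       indels_gt5 = sum(per$indels_gt5))
}

#' @export
print.closure_eval <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "closure evaluation: %d gaps — %d closed (%d perfect), %d partial, %d open\n",
    t$gaps, t$closed, t$perfect, t$partial, t$open))
  cat(sprintf("errors in closed gaps: %d SNPs, %d indels <=5 bp, %d indels >5 bp\n",
              t$snps, t$indels_le5, t$indels_gt5))
  invisible(x)
}

#' Write a closure evaluation as JSON
#' @param eval A [evaluate_closure()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(eval, path) {
  jsonlite::write_json(list(totals = eval$totals, gaps = eval$gaps), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
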