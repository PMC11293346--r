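## Aggregation: the outcome report and the productive-integration
## arithmetic used to reconcile integration-event fractions with
## transgene-positive cell counts.

#' Total ITR-free integration percentage
#'
#' Sum of the integration-event peak fractions that represent cleaved
#' (ITR-free) donor integration, in percent.
#'
#' @param peak_fractions numeric vector of percentages (each \code{>= 0});
#'   an empty vector totals 0.
#' @return percentage.
#' @export
itr_free_total <- function(peak_fractions) {
  if (length(peak_fractions) == 0L) return(0)
  if (any(peak_fractions < 0)) stop("peak fractions must be >= 0")
  sum(peak_fractions)
}

#' Productive integration percentage
#'
#' The share of ITR-free integration events that are productive (forward
#' orientation with an intact splice-trap payload), applied to the
#' ITR-free total; rendered to one decimal, matching how such percentages
#' are reported.
#'
#' @param itr_free_total percentage from \code{\link{itr_free_total}}.
#' @param productive_share fraction in [0, 1].
#' @return percentage, rounded to one decimal.
#' @export
productive_fraction <- function(itr_free_total, productive_share) {
  if (productive_share < 0 || productive_share > 1)
    stop("productive_share must lie in [0, 1]")
  round(itr_free_total * productive_share, 1)
}

#' Map simulation truth classes to expected classifier calls
#'
#' @param class character vector of truth outcome classes.
#' @return character vector of expected read-level calls (\code{NA} for
#'   classes whose junction product is not an amplifiable template, i.e.
#'   large deletions/inversions).
#' @export
map_truth_to_call <- function(class) {
  m <- c(unedited = "unedited", nhej_indel = "nhej_indel",
         hiti_forward = "hiti_clean", hiti_reverse = "reverse_orientation",
         itr_retained_forward = "itr_containing",
         itr_retained_reverse = "itr_containing",
         itr_fragment_capture = "itr_containing",
         cas9_fragment_capture = "nhej_indel",
         large_deletion = NA_character_, large_inversion = NA_character_)
  unname(m[class])
}

#' Confusion matrix of calls against simulation truth
#'
#' @param classifications data frame from \code{\link{classify_reads}}.
#' @param truth truth table from \code{\link{simulate_reads}} (matched by
#'   read_id).
#' @return list with \code{matrix} (expected x called counts),
#'   \code{misclassification_rate} (fraction of reads whose call differs
#'   from the expected call, over reads with a defined expectation) and
#'   \code{per_class_error} (absolute recovery error per expected class).
#' @export
truth_confusion <- function(classifications, truth) {
  i <- match(classifications$read_id, truth$read_id)
  if (anyNA(i)) stop("classifications contain read ids absent from truth")
  expected <- map_truth_to_call(truth$class[i])
  called <- classifications$class
  keep <- !is.na(expected)
  lev <- sort(unique(c(expected[keep], called[keep])))
  mat <- table(factor(expected[keep], lev), factor(called[keep], lev))
  names(dimnames(mat)) <- c("expected", "called")
  exp_frac <- prop.table(table(factor(expected[keep], lev)))
  call_frac <- prop.table(table(factor(called[keep], lev)))
  list(matrix = mat,
       misclassification_rate = mean(expected[keep] != called[keep]),
       per_class_error = abs(as.numeric(call_frac) - as.numeric(exp_frac)) |>
         setNames(lev))
}

check_fraction_block <- function(x, what) {
  s <- sum(unlist(x))
  if (abs(s - 1) > 1e-9)
    stop(what, " fractions must sum to 1 (got ", s, ")")
  x
}

#' Aggregate results into an outcome report
#'
#' Merges whichever blocks are available (at least one is required):
#' long-read per-side class fractions, the amplicon indel fraction, the
#' short-read ITR frequency, and integration-event (peak) fractions with
#' the productive-share arithmetic.  When simulation truth is supplied the
#' report additionally carries the confusion matrix and per-class
#' recovery errors.
#'
#' @param long_read summary data frame from
#'   \code{\link{summarize_junctions}}.
#' @param indel result of \code{\link{call_amplicon_indels}}.
#' @param short_read result of \code{\link{quantify_itr_short_reads}}.
#' @param peak_fractions numeric vector of ITR-free integration-event
#'   percentages.
#' @param productive_share fraction in [0, 1].
#' @param classifications,truth per-read calls and simulation truth for
#'   the confusion block.
#' @param metadata named list (seeds, thresholds, ...) recorded verbatim.
#' @return an \code{OutcomeReport} (a list; serialise with
#'   \code{\link{write_outcome_report}}).
#' @export
aggregate_report <- function(long_read = NULL, indel = NULL,
                             short_read = NULL, peak_fractions = NULL,
                             productive_share = NULL,
                             classifications = NULL, truth = NULL,
                             metadata = list()) {
  if (is.null(long_read) && is.null(indel) && is.null(short_read) &&
      is.null(peak_fractions))
    stop("at least one input block is required")
  rep <- list(schema = "hitiseq_outcome_report/1")
  if (!is.null(long_read)) {
    lr <- lapply(split(long_read, long_read$side), function(s) {
      cl <- s[s$class != "unassigned", ]
      check_fraction_block(setNames(as.list(cl$fraction), cl$class),
                           paste0("long-read side ", s$side[1L]))
    })
    rep$long_read <- lr
    una <- long_read[long_read$class == "unassigned", ]
    rep$long_read_unassigned <- setNames(as.list(una$fraction_incl_unassigned),
                                         una$side)
  }
  if (!is.null(indel))
    rep$amplicon_indel <- list(modified_fraction = indel$modified_fraction,
                               n_aligned = indel$n_aligned,
                               n_excluded = indel$n_excluded)
  if (!is.null(short_read))
    rep$short_read_itr <- list(frequency = short_read$frequency,
                               n_mapped = short_read$n_mapped,
                               n_itr = short_read$n_itr)
  if (!is.null(peak_fractions)) {
    total <- itr_free_total(peak_fractions)
    rep$integration_events <- list(
      peak_fractions = as.numeric(peak_fractions),
      itr_free_total = total)
    if (!is.null(productive_share)) {
      rep$integration_events$productive_share <- productive_share
      rep$integration_events$productive_total <-
        productive_fraction(total, productive_share)
    }
  }
  if (!is.null(classifications) && !is.null(truth)) {
    conf <- truth_confusion(classifications, truth)
    rep$truth_comparison <- list(
      confusion = as.data.frame.matrix(unclass(conf$matrix)) |>
        (\(d) { d$expected <- rownames(d); rownames(d) <- NULL; d })(),
      misclassification_rate = conf$misclassification_rate,
      per_class_error = as.list(conf$per_class_error))
  }
  rep$metadata <- c(metadata, list(package_version =
                                     as.character(packageVersion("hitiseq"))))
  structure(rep, class = "OutcomeReport")
}

#' Write / read an outcome report as JSON
#'
#' Serialisation is stable: writing, reading and writing again produces
#' byte-identical JSON.
#'
#' @param report an \code{OutcomeReport}.
#' @param path JSON file.
#' @export
write_outcome_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_outcome_report
#' @export
read_outcome_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE),
            class = "OutcomeReport")
}

#' @export
print.OutcomeReport <- function(x, ...) {
  cat("hitiseq outcome report\n")
  if (!is.null(x$long_read)) {
    for (side in names(x$long_read)) {
      cat("  long-read junction (", side, "):\n", sep = "")
      fr <- x$long_read[[side]]
      for (cl in names(fr))
        cat(sprintf("    %-20s %5.1f%%\n", cl, 100 * as.numeric(fr[[cl]])))
    }
  }
  if (!is.null(x$amplicon_indel))
    cat(sprintf("  amplicon modified reads: %.1f%% (n=%d)\n",
                100 * x$amplicon_indel$modified_fraction,
                x$amplicon_indel$n_aligned))
  if (!is.null(x$short_read_itr))
    cat(sprintf("  short-read ITR frequency: %.1f%% (%d/%d)\n",
                100 * x$short_read_itr$frequency, x$short_read_itr$n_itr,
                x$short_read_itr$n_mapped))
  if (!is.null(x$integration_events)) {
    ie <- x$integration_events
    cat(sprintf("  ITR-free integration total: %.1f%%\n", ie$itr_free_total))
    if (!is.null(ie$productive_total))
      cat(sprintf("  productive integration:     %.1f%% (%.0f%% of %.1f%%)\n",
                  ie$productive_total, 100 * ie$productive_share,
                  ie$itr_free_total))
  }
  if (!is.null(x$truth_comparison))
    cat(sprintf("  misclassification vs truth: %.2f%%\n",
                100 * x$truth_comparison$misclassification_rate))
  invisible(x)
}
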