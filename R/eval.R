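#' Entity-linking accuracy for one record
#'
#' The proportion of gold CUIs the system returned:
#' \deqn{Accuracy = |G \cap R| / |G|}
#' Set semantics on both sides; a mention may legitimately carry several
#' valid CUIs (e.g. "chemotherapy" maps to C0013216, C3665472 and
#' C1571591), which is why plain precision/recall on a single CUI does
#' not fit.
#'
#' @param gold non-empty character vector of gold CUIs.
#' @param returned character vector of returned CUIs.
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(gold, returned) {
  gold <- unique(as.character(gold))
  if (length(gold) == 0L) stop("accuracy is undefined for an empty gold set")
  length(intersect(gold, unique(as.character(returned)))) / length(gold)
}

#' Accuracy at N
#'
#' As [accuracy()], restricted to the top `n` of a ranked CUI list
#' (deduplicated preserving first occurrence):
#' \deqn{Accuracy@N = |G \cap R_{top\mbox{-}N}| / |G|}
#'
#' @param gold non-empty character vector of gold CUIs.
#' @param ranked ranked CUI list, best first.
#' @param n cut-off, `n >= 1`.
#' @return accuracy in \[0, 1\]; non-decreasing in `n`.
#' @export
accuracy_at_n <- function(gold, ranked, n) {
  stopifnot(n >= 1L)
  ranked <- unique(as.character(ranked))
  accuracy(gold, utils::head(ranked, n))
}

#' Load a gold benchmark file
#'
#' JSON-lines records with fields `text`, `context`, `cuis` (capitalized
#' variants `Text`/`Context`/`CUIs` tolerated). Duplicate
#' (normalized text, context) pairs are rejected: a benchmark lists each
#' mention/context pair once.
#'
#' @param path gold file.
#' @return data frame `text, context` with list column `cuis`.
#' @export
load_gold <- function(path) {
  recs <- read_jsonl(path)
  get <- function(r, a, b) r[[a]] %||% r[[b]]
  df <- data.frame(
    text = vapply(recs, function(r) as.character(get(r, "text", "Text")), ""),
    context = vapply(recs, function(r)
      as.character(get(r, "context", "Context")), ""),
    stringsAsFactors = FALSE)
  df$cuis <- lapply(recs, function(r)
    unique(as.character(unlist(get(r, "cuis", "CUIs")))))
  if (any(lengths(df$cuis) == 0L)) stop("gold record with empty CUI set")
  key <- paste(normalize_text(df$text), df$context, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (text, context) records in gold")
  df
}

#' Evaluate predictions against a gold benchmark
#'
#' Records are matched by (normalized mention text, context label). Every
#' gold record must be matched or it is scored 0 and listed as missing —
#' silent drops are penalized, not skipped. Mean accuracy and mean
#' Accuracy@N are unweighted over gold records.
#'
#' @param pred a `pipeline_run`, its `records`, or the path of a
#'   JSON-lines predictions file with fields `surface` (or `text`),
#'   `label` (or `context`), `cuis`, `ranked_cuis`, `status`.
#' @param gold a [load_gold()] data frame or a gold file path.
#' @param n_values Accuracy@N cut-offs to report (default 1, 5, 15).
#' @return an `eval_report`: list with `per_record` (data frame),
#'   `mean_accuracy`, `accuracy_at` (named vector), `status_counts`,
#'   `missing` (unmatched gold texts), `n_gold`, `n_matched`.
#' @export
evaluate <- function(pred, gold, n_values = c(1L, 5L, 15L)) {
  if (inherits(pred, "pipeline_run")) pred <- pred$records
  if (is.character(pred) && length(pred) == 1L) pred <- read_jsonl(pred)
  if (is.character(gold) && length(gold) == 1L) gold <- load_gold(gold)
  stopifnot(is.data.frame(gold), nrow(gold) > 0L)

  pkey <- vapply(pred, function(p) paste(
    normalize_text(p$surface %||% p$text),
    p$label %||% p$context, sep = "\r"), "")
  # first prediction wins for a repeated mention/context pair
  first <- !duplicated(pkey)
  pred <- pred[first]; pkey <- pkey[first]
  gkey <- paste(normalize_text(gold$text), gold$context, sep = "\r")
  pos <- match(gkey, pkey)
  if (all(is.na(pos))) stop("no gold record matched any prediction")

  rows <- lapply(seq_len(nrow(gold)), function(i) {
    g <- gold$cuis[[i]]
    if (is.na(pos[i])) {
      return(data.frame(text = gold$text[i], context = gold$context[i],
                        matched = FALSE, accuracy = 0,
                        t(stats::setNames(rep(0, length(n_values)),
                                          paste0("acc_at_", n_values))),
                        status = NA_character_, stringsAsFactors = FALSE))
    }
    p <- pred[[pos[i]]]
    ret <- unique(as.character(unlist(p$cuis)))
    ranked <- unique(as.character(unlist(p$ranked_cuis %||% p$cuis)))
    at <- vapply(n_values, function(n) accuracy_at_n(g, ranked, n), 0)
    data.frame(text = gold$text[i], context = gold$context[i],
               matched = TRUE, accuracy = accuracy(g, ret),
               t(stats::setNames(at, paste0("acc_at_", n_values))),
               status = p$status %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  per_record <- do.call(rbind, rows)
  at_means <- vapply(paste0("acc_at_", n_values), function(cn)
    mean(per_record[[cn]]), 0)
  names(at_means) <- paste0("accuracy_at_", n_values)
  statuses <- per_record$status[!is.na(per_record$status)]
  structure(list(
    per_record = per_record,
    mean_accuracy = mean(per_record$accuracy),
    accuracy_at = at_means,
    status_counts = as.list(table(statuses)),
    missing = gold$text[is.na(pos)],
    n_gold = nrow(gold),
    n_matched = sum(!is.na(pos))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d/%d gold records matched\n", x$n_matched,
              x$n_gold))
  cat(sprintf("  mean accuracy: %.4f\n", x$mean_accuracy))
  for (nm in names(x$accuracy_at)) {
    cat(sprintf("  %s: %.4f\n", nm, x$accuracy_at[[nm]]))
  }
  invisible(x)
}

#' Sweep pipeline configurations
#'
#' Runs the pipeline once per configuration and evaluates each run against
#' the gold benchmark — the harness behind query-type, threshold and
#' prompt ablations. Per-config failures are recorded in the table and the
#' sweep continues.
#'
#' @param configs named list of [pipeline_config()]s.
#' @param corpus,index,client,recognizer,acronym_dict as [run_pipeline()].
#' @param gold gold benchmark (path or data frame).
#' @param n_values Accuracy@N cut-offs.
#' @return data frame: one row per config with mean accuracy, Accuracy@N
#'   columns, LLM call counts, and an `error` column (NA on success);
#'   rows in the order of `configs`.
#' @export
sweep_configs <- function(configs, corpus, index, gold, client = NULL,
                          recognizer, acronym_dict = default_acronyms(),
                          n_values = c(1L, 5L, 15L)) {
  stopifnot(length(configs) > 0L)
  nm <- names(configs) %||% as.character(seq_along(configs))
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    out <- tryCatch({
      run <- run_pipeline(corpus, index, cfg, client, recognizer,
                          acronym_dict)
      ev <- evaluate(run, gold, n_values)
      cbind(data.frame(config = nm[i], q_type = cfg$q_type,
                       theta_sim = cfg$theta_sim,
                       prompt_style = cfg$prompt_style,
                       mean_accuracy = ev$mean_accuracy,
                       stringsAsFactors = FALSE),
            t(ev$accuracy_at),
            data.frame(
              llm_calls = run$report$llm_disambiguation_calls,
              error = NA_character_, stringsAsFactors = FALSE))
    }, error = function(e) {
      df <- data.frame(config = nm[i], q_type = cfg$q_type,
                       theta_sim = cfg$theta_sim,
                       prompt_style = cfg$prompt_style,
                       mean_accuracy = NA_real_, stringsAsFactors = FALSE)
      for (n in n_values) df[[paste0("accuracy_at_", n)]] <- NA_real_
      df$llm_calls <- NA_integer_
      df$error <- conditionMessage(e)
      df
    })
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
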