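#' Assemble cascade resources from a study bundle
#' @param study An `hlof_study` (or the list returned by [read_study()]).
#' @return list usable as the `resources` argument of [run_cascade()].
#' @export
study_resources <- function(study) {
  list(tracks = study$tracks, primates = study$primates,
       transcripts = study$transcripts, callset = study$callset)
}

#' Identify candidates and run the filter cascade on a study bundle
#'
#' @param study An `hlof_study` (or [read_study()] output).
#' @param opts [cascade_options()].
#' @return list with `candidates` plus the [run_cascade()] results
#'   (`survivors`, `survivor_candidates`, `decisions`, `audit`).
#' @export
scan_study <- function(study, opts = cascade_options()) {
  cands <- identify_candidates(
    study$callset, study$transcripts,
    known_catalogue = study$tables$known_catalogue,
    cscores = study$tables$cscores, min_depth = opts$min_depth)
  res <- run_cascade(cands, study_resources(study), opts)
  c(list(candidates = cands), res)
}

#' Compare cascade results against a planted truth table
#'
#' @param scan Result of [scan_study()].
#' @param truth Truth table (`key`, `category`, `intended_filter`).
#' @return list with `sensitivity` (fraction of true HLOFs surviving),
#'   `per_category` (data.frame: planted, removed, removed_by_intended
#'   counts per artifact category) and `candidate_keys`.
#' @export
evaluate_against_truth <- function(scan, truth) {
  cand_keys <- vapply(scan$candidates, `[[`, character(1), "key")
  fails <- failing_filters(scan$decisions)
  true_keys <- truth$key[truth$category == "TRUE_HLOF"]
  sens <- mean(true_keys %in% scan$survivors)
  cats <- setdiff(unique(truth$category), "TRUE_HLOF")
  per_cat <- do.call(rbind, lapply(cats, function(cc) {
    sub <- truth[truth$category == cc, , drop = FALSE]
    if (cc == "INFRAME") {
      removed <- !(sub$key %in% cand_keys)
      by_intended <- removed
    } else {
      removed <- !(sub$key %in% scan$survivors)
      by_intended <- vapply(seq_len(nrow(sub)), function(i) {
        identical(unname(fails[[sub$key[i]]]), sub$intended_filter[i])
      }, logical(1))
    }
    data.frame(category = cc, planted = nrow(sub), removed = sum(removed),
               removed_by_intended_only = sum(by_intended),
               stringsAsFactors = FALSE)
  }))
  list(sensitivity = sens, per_category = per_cat,
       candidate_keys = cand_keys)
}
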