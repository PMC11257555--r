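#' @include containers.R
NULL

#' Selection policy for independent biospecimens
#'
#' @param strategyFilter experimental strategies to allow (default all).
#' @param descriptorPreference ordered tumor-descriptor preference;
#'   earlier entries win. Descriptors not listed rank after all listed
#'   ones.
#' @param tieBreak column used as final deterministic key (default
#'   `sample_id`, ascending).
#' @return named list (the policy).
#' @export
selectionPolicy <- function(strategyFilter = NULL,
                            descriptorPreference = c(
                              "Initial CNS Tumor", "Primary Tumor",
                              "Progressive", "Recurrence"),
                            tieBreak = "sample_id") {
  list(strategy_filter = strategyFilter,
       descriptor_preference = descriptorPreference,
       tie_break = tieBreak)
}

#' Select one independent biospecimen per participant
#'
#' Filters to the allowed experimental strategies, then picks exactly one
#' specimen per participant by descriptor preference order, breaking
#' remaining ties on the policy's tie-break column (lexicographic
#' ascending). Participants with no qualifying specimen are omitted (and
#' reported via `message()`). Idempotent: re-selecting from the output
#' returns it unchanged.
#'
#' @param specimens `data.frame` with `sample_id`, `participant_id`,
#'   `experimental_strategy`, `tumor_descriptor`.
#' @param policy from [selectionPolicy()].
#' @return subset of `specimens`, one row per participant.
#' @export
selectIndependent <- function(specimens, policy = selectionPolicy()) {
  df <- as.data.frame(specimens)
  all_participants <- unique(df$participant_id)
  if (!is.null(policy$strategy_filter)) {
    df <- df[df$experimental_strategy %in% policy$strategy_filter, ,
             drop = FALSE]
  }
  dropped <- setdiff(all_participants, unique(df$participant_id))
  if (length(dropped)) {
    message(length(dropped), " participant(s) with no qualifying ",
            "specimen omitted: ", paste(dropped, collapse = ", "))
  }
  if (!nrow(df)) return(df)
  pref <- match(df$tumor_descriptor, policy$descriptor_preference)
  pref[is.na(pref)] <- length(policy$descriptor_preference) + 1L
  ord <- order(df$participant_id, pref, df[[policy$tie_break]],
               method = "radix")
  out <- df[ord, , drop = FALSE]
  out <- out[!duplicated(out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
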