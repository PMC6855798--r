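#' Simulate head-motion parameter traces
#'
#' Random-walk translations (mm) and rotations (rad) with occasional
#' motion spikes, one time x 6 matrix per scan (columns: x, y, z
#' translations then roll, pitch, yaw rotations).
#'
#' @param design Scan table from [make_design()].
#' @param n_frames Frames per scan.
#' @param seed Integer seed.
#' @param step_sd_mm,step_sd_rad Random-walk step SDs.
#' @param spike_prob Per-frame probability of a translation spike.
#' @param spike_mm Spike amplitude in mm.
#' @return Named list of `n_frames x 6` matrices keyed by `scan_id`.
#' @export
simulate_motion <- function(design, n_frames = 300, seed = 1L,
                            step_sd_mm = 0.02, step_sd_rad = 2e-4,
                            spike_prob = 0.01, spike_mm = 0.4) {
  with_seed(seed, {
    out <- vector("list", nrow(design))
    names(out) <- design$scan_id
    for (i in seq_len(nrow(design))) {
      steps <- cbind(matrix(rnorm(n_frames * 3, 0, step_sd_mm), n_frames),
                     matrix(rnorm(n_frames * 3, 0, step_sd_rad), n_frames))
      spikes <- which(runif(n_frames) < spike_prob)
      steps[spikes, 1] <- steps[spikes, 1] + spike_mm * sign(rnorm(length(spikes)))
      m <- apply(steps, 2, cumsum)
      colnames(m) <- c("trans_x", "trans_y", "trans_z",
                       "rot_roll", "rot_pitch", "rot_yaw")
      out[[i]] <- m
    }
    out
  })
}

#' Simulate memory-task trials coupled to connectivity effects
#'
#' For each subject and assessment (`pre_stim`, `post_stim`, `pre_sham`,
#' `post_sham`) generates an 84-trial recognition test (42 studied, 42 new
#' objects).  Old/new responses are correct with probability `p_item`;
#' correct old responses are high-confidence with probability
#' `p_highconf`; the studied context (one of six options) is chosen
#' correctly with a per-assessment probability.  The generating
#' context-recollection change, `post_stim` minus `post_sham`, equals
#' `behavior_slope * interaction_effect + Gaussian(0, behavior_sd)`,
#' truncated so all probabilities stay in `[0, 1]`.
#'
#' @param design Scan table from [make_design()] (one row per scan; the
#'   subject list is taken from it).
#' @param interaction_effects Named numeric vector, one connectivity
#'   interaction effect per subject (names = subject ids).
#' @param effects An [effect_spec()] supplying `behavior_slope` and
#'   `behavior_sd`.
#' @param seed Integer seed.
#' @param n_items Studied objects per assessment (default 42).
#' @param p_item Probability of a correct old/new response.
#' @param p_highconf Probability that a hit is high-confidence.
#' @param p_context_base Baseline probability of recalling the correct
#'   context; `"guessing"` behaviour corresponds to 1/6.
#' @return List with `trials` (trial-level tibble), `scores` (per subject
#'   x assessment [score_memory()] output) and `true_change` (the
#'   generating per-subject context-recollection change).
#' @export
simulate_behavior <- function(design, interaction_effects, effects = effect_spec(),
                              seed = 1L, n_items = 42, p_item = 0.85,
                              p_highconf = 0.7, p_context_base = 0.35) {
  subjects <- unique(design$subject_id)
  if (is.null(names(interaction_effects)) ||
      !all(as.character(subjects) %in% names(interaction_effects))) {
    abort("`interaction_effects` must be named with every subject id.")
  }
  assessments <- c("pre_stim", "post_stim", "pre_sham", "post_sham")
  with_seed(seed, {
    change <- effects$behavior_slope * interaction_effects[as.character(subjects)] +
      rnorm(length(subjects), 0, effects$behavior_sd)
    trials <- purrr::map(seq_along(subjects), function(si) {
      sid <- subjects[si]
      purrr::map(assessments, function(a) {
        p_ctx <- p_context_base + if (a == "post_stim") change[si] else 0
        p_ctx <- min(max(p_ctx, 0), 1)  # truncation keeps proportions feasible
        simulate_assessment_trials(sid, a, n_items, p_item, p_highconf, p_ctx)
      }) |> list_rbind()
    }) |> list_rbind()
    scores <- trials |>
      group_by(.data$subject_id, .data$assessment) |>
      group_modify(~score_memory(.x)) |>
      ungroup()
    list(trials = trials, scores = scores,
         true_change = tibble(subject_id = subjects,
                              context_change = unname(change)))
  })
}

simulate_assessment_trials <- function(subject_id, assessment, n_items,
                                       p_item, p_highconf, p_ctx) {
  n_trials <- 2L * n_items
  is_old <- rep(c(TRUE, FALSE), each = n_items)
  correct_itemwise <- runif(n_trials) < p_item
  # response is "old" when (old & correct) or (new & incorrect)
  response <- ifelse(is_old, ifelse(correct_itemwise, "old", "new"),
                     ifelse(correct_itemwise, "new", "old"))
  confidence <- ifelse(response == "old" & is_old & runif(n_trials) < p_highconf,
                       "high", "low")
  true_context <- ifelse(is_old, sample(6, n_trials, replace = TRUE), NA)
  ctx_correct <- runif(n_trials) < p_ctx
  context_choice <- ifelse(
    is_old,
    ifelse(ctx_correct, true_context,
           # uniform among the five wrong options
           1L + (true_context - 1L + sample(5, n_trials, replace = TRUE)) %% 6L),
    NA)
  tibble(subject_id = subject_id, assessment = assessment,
         trial = seq_len(n_trials), is_old = is_old,
         response = response, confidence = confidence,
         true_context = as.integer(true_context),
         context_choice = as.integer(context_choice))
}
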