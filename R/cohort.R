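# Synthetic two-session measurement cohorts at the static-measure level:
# each subject is the face template with a subject-specific landmark
# perturbation (anatomy varies between people), measured twice with
# independent per-session placement/measurement noise.

#' Simulate a two-session static-measure cohort
#'
#' Draws `n_subjects` synthetic faces (the rest template plus an
#' independent Gaussian per-coordinate subject offset with SD
#' `sigma_between_mm`), measures each face twice with independent
#' per-session landmark noise of SD `sigma_within_mm`, and computes the
#' 20-parameter static measure set in each session's anatomical frame.
#'
#' @param n_subjects cohort size (the reliability study used 19).
#' @param sigma_between_mm between-subject landmark SD (mm).
#' @param sigma_within_mm within-subject per-session landmark SD (mm).
#' @param seed RNG seed.
#' @param face template face, by default [face_template()].
#' @return A list of two data.frames (`session1`, `session2`) with columns
#'   `subject`, `parameter`, `class`, `value`, ready for
#'   [reliability_table()].
#' @export
simulate_static_cohort <- function(n_subjects = 19, sigma_between_mm = 3,
                                   sigma_within_mm = 0.3, seed = 1,
                                   face = face_template()) {
  rest <- face_points(face)[face$type == "face", ]
  with_seed(seed, {
    sessions <- list(NULL, NULL)
    for (subj in seq_len(n_subjects)) {
      offs <- matrix(rnorm(length(rest), 0, sigma_between_mm), nrow(rest), 3)
      subject_face <- rest + offs
      for (s in 1:2) {
        noisy <- subject_face +
          matrix(rnorm(length(rest), 0, sigma_within_mm), nrow(rest), 3)
        fr <- anatomical_frame(noisy)
        anat <- to_frame_coords(fr, noisy)
        rownames(anat) <- rownames(rest)
        meas <- static_measures(anat)
        meas$subject <- subj
        sessions[[s]] <- rbind(sessions[[s]], meas)
      }
    }
    list(session1 = sessions[[1]], session2 = sessions[[2]])
  })
}
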