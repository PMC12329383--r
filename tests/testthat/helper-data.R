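# compact builders for hand-made datasets

obs_row <- function(pid, measure, week, phase, value) {
  data.frame(participant_id = pid, measure = measure, week_index = week,
             phase = phase, value = value, stringsAsFactors = FALSE)
}

# two-phase weekly series for one participant
weekly_series <- function(pid, measure, a_values, b_values,
                          phase_b = "B") {
  rbind(
    obs_row(pid, measure, seq_along(a_values) - 1L, "A", a_values),
    obs_row(pid, measure, length(a_values) + seq_along(b_values) - 1L,
            phase_b, b_values)
  )
}

# minimal sessions table from composite targets: puts the whole positive
# composite into labeled_praise and the negative one into question
sessions_from_composites <- function(pid, pf, nl, vr) {
  data.frame(participant_id = pid, session_index = seq_along(pf),
             labeled_praise = pf, unlabeled_praise = 0L, reflection = 0L,
             behavior_description = 0L, question = nl, direct_command = 0L,
             indirect_command = 0L, negative_talk = 0L,
             vr_practices_since_previous = vr, stringsAsFactors = FALSE)
}
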