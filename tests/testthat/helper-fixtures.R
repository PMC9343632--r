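# shared fixture builders (everything is generated in code; no stored data)

# list of schema_activation objects from an utterance x 9 ordinal matrix
activations_from_ordinal <- function(m) {
  lapply(seq_len(nrow(m)), function(i) {
    schema_activation(paste0("u", i), m[i, ] / 3)
  })
}

# a persona whose utterances use only one schema's vocabulary
single_schema_persona <- function(s, depth = 3) {
  w <- numeric(9)
  w[s] <- 1
  persona_config(schema_profile = w, chain_depth_distribution = depth)
}

# small, separable-by-construction training corpus
training_corpus <- function(n = 400, seed = 42) {
  generate_labelled_corpus(persona_config(), n, seed = seed)
}

# complete one scripted session and return the final state
complete_session <- function(session, condition, persona, seed,
                             n_records = 1) {
  res <- start_session(session, condition, seed = seed)
  script <- generate_transcript_script(persona, session,
                                       n_records = n_records,
                                       seed = seed + 1)
  run_script(res$state, script)
}
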