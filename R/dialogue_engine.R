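#' @name dialogue_engine
#' @title Deterministic thought-recording dialogue engine
#'
#' @description
#' A finite-state conversation that elicits thought records: the agent asks
#' for the four core fields in a fixed order (situation, emotion, automatic
#' thought, behavior), then runs the downward-arrow loop from the automatic
#' thought, then shows the condition's feedback bundle and asks whether to
#' continue. Session 1 consists of exactly two scenario-based records;
#' session 2 starts directly with a personal record and lets the user
#' complete as many records as they want (at least one).
#'
#' All interaction outside the thought-record fields and the downward-arrow
#' loop uses enumerated button tokens (`"ready"`, `"ok"`, `"yes"`, `"no"`,
#' and the downward-arrow stop token), so the engine is interface-agnostic.
#' Given the same seed and input script, a session replays byte-identically;
#' timestamps are a logical event counter, not wall-clock time.
NULL

BUTTON_TOKENS <- c("ready", "ok", "yes", "no")
FREE_TEXT_PHASES <- c("ask_situation", "ask_emotion", "ask_thought",
                      "ask_behavior", "downward_arrow")

#' Built-in scenario library
#'
#' Ten practice scenarios for session 1, split into five interpersonally
#' difficult and five achievement-related situations. The shipped wording is
#' a placeholder set in the spirit of standard cognitive-error and
#' ways-of-responding vignettes; studies should supply their own YAML
#' library via [read_scenarios()].
#'
#' @return data.frame with columns `scenario_id`, `category`, `text`.
#' @export
default_scenario_library <- function() {
  data.frame(
    scenario_id = c(paste0("int", 1:5), paste0("ach", 1:5)),
    category = rep(c("interpersonal", "achievement"), each = 5L),
    text = c(
      "An acquaintance walks past you on the street and does not wave back.",
      "A close friend cancels your plans for the third time in a row.",
      "At a party, the conversation stops when you join the group.",
      "Your partner seems distant and answers you in single words all evening.",
      "A family member criticizes how you handled a personal decision.",
      "You are let go from your new job for not meeting your quota.",
      "You receive a failing grade on an exam you studied hard for.",
      "Your project proposal is rejected in front of the whole team.",
      "You miss an important deadline despite working late all week.",
      "A colleague hired after you is promoted ahead of you."
    ),
    stringsAsFactors = FALSE
  )
}

#' Read a scenario library from YAML
#'
#' The file is a list of entries with fields `scenario_id` (or `id`),
#' `category` (`interpersonal` or `achievement`) and `text`.
#'
#' @param path YAML file.
#' @return data.frame with columns `scenario_id`, `category`, `text`.
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("scenario library is empty")
  rows <- lapply(raw, function(x) {
    id <- x$scenario_id
    if (is.null(id)) id <- x$id
    if (is.null(id) || is.null(x$category) || is.null(x$text)) {
      stop("each scenario needs scenario_id (or id), category and text")
    }
    data.frame(scenario_id = as.character(id),
               category = as.character(x$category),
               text = as.character(x$text), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

validate_scenario_library <- function(library) {
  if (!is.data.frame(library) ||
      !all(c("scenario_id", "category", "text") %in% names(library))) {
    stop("scenario library must have columns scenario_id, category, text")
  }
  if (anyDuplicated(library$scenario_id)) stop("scenario ids must be unique")
  tab <- table(factor(library$category,
                      levels = c("interpersonal", "achievement")))
  if (!all(tab == 5L)) {
    stop("scenario library must contain exactly 5 interpersonal and 5 ",
         "achievement scenarios, got ", tab[["interpersonal"]], " and ",
         tab[["achievement"]])
  }
  invisible(library)
}

#' Select the two practice scenarios for session 1
#'
#' Draws one scenario uniformly at random from each of the two category
#' sets; the order in which the two categories are presented is also
#' randomized. Uses the current RNG state (callers seed it).
#'
#' @param library A validated scenario library.
#' @return Character vector of two scenario ids, in presentation order.
#' @export
select_scenarios <- function(library) {
  validate_scenario_library(library)
  pick <- function(cat) {
    ids <- library$scenario_id[library$category == cat]
    ids[sample.int(length(ids), 1L)]
  }
  pair <- c(interpersonal = pick("interpersonal"),
            achievement = pick("achievement"))
  unname(pair[sample.int(2L)])
}

default_dialogue_config <- function() {
  list(
    probe_question = "If that were true, what would that mean about you?",
    stop_token = "done",
    max_depth = 25L,
    onboarding = paste("Hi, I am Luca, a chatbot that will guide you through",
                       "a thought-recording exercise."),
    instructions = paste("We will go through emotionally difficult",
                         "situations step by step: what happened, how you",
                         "felt, what you thought, and what you did. We will",
                         "then dig deeper into the thought together."),
    welcome_back = paste("Welcome back! Today you will record thoughts about",
                         "situations from your own life.")
  )
}

new_event <- function(role, phase, text, t) {
  list(role = role, phase = phase, text = text, t = t)
}

say <- function(state, text) {
  state$clock <- state$clock + 1L
  state$transcript[[length(state$transcript) + 1L]] <-
    new_event("agent", state$phase, text, state$clock)
  state$pending <- c(state$pending, text)
  state
}

hear <- function(state, text) {
  state$clock <- state$clock + 1L
  state$transcript[[length(state$transcript) + 1L]] <-
    new_event("user", state$phase, text, state$clock)
  state
}

reply <- function(state) {
  msgs <- state$pending
  state$pending <- character()
  list(state = state, messages = msgs)
}

#' Start a thought-recording session
#'
#' @param session_index 1 (two mandatory scenario-based records) or 2
#'   (personal records, at least one, as many as wanted).
#' @param condition Feedback richness: `"low"`, `"medium"` or `"high"`.
#' @param scenario_library Library for session 1 (ignored in session 2);
#'   must contain 5 interpersonal + 5 achievement scenarios.
#' @param seed Integer seed; the only randomness is scenario selection.
#' @param participant_id Identifier stamped on records.
#' @param scorer Optional `schema_scorer`; required for the high condition
#'   (defaults to [lexicon_scorer()] in that case).
#' @param reference Step-count reference distribution for medium/high.
#' @param schemas A [schema_set()].
#' @param config Engine wording/limits, see `default_dialogue_config()`.
#' @return List with elements `state` (a `dialogue_state`) and `messages`
#'   (the agent's opening messages).
#' @export
start_session <- function(session_index, condition,
                          scenario_library = default_scenario_library(),
                          seed = 1L, participant_id = "p1", scorer = NULL,
                          reference = default_reference_distribution(),
                          schemas = default_schema_set(),
                          config = default_dialogue_config()) {
  session_index <- as.integer(session_index)
  if (!session_index %in% c(1L, 2L)) stop("session_index must be 1 or 2")
  condition <- match.arg(condition, c("low", "medium", "high"))
  if (condition == "high" && is.null(scorer)) scorer <- lexicon_scorer(schemas)
  state <- structure(list(
    phase = "onboarding", session_index = session_index,
    condition = condition, participant_id = participant_id,
    current = NULL, completed_records = list(),
    scenario_queue = character(), scenario_library = NULL,
    clock = 0L, transcript = list(), pending = character(),
    rng_seed = as.integer(seed), scorer = scorer, reference = reference,
    schemas = schemas, config = config, last_feedback = NULL
  ), class = "dialogue_state")
  if (session_index == 1L) {
    validate_scenario_library(scenario_library)
    state$scenario_library <- scenario_library
    set.seed(state$rng_seed)
    state$scenario_queue <- select_scenarios(scenario_library)
    state <- say(state, config$onboarding)
    state$phase <- "instructions"
    state <- say(state, config$instructions)
    state <- enter_scenario_presentation(state)
  } else {
    state <- say(state, config$welcome_back)
    state <- begin_record(state)
  }
  reply(state)
}

enter_scenario_presentation <- function(state) {
  state$phase <- "scenario_presentation"
  id <- state$scenario_queue[1L]
  text <- state$scenario_library$text[state$scenario_library$scenario_id == id]
  state <- say(state, paste0("Please imagine the following situation: ", text))
  say(state, "Press [ready] when you have put yourself in the situation.")
}

begin_record <- function(state) {
  origin <- if (state$session_index == 1L) "scenario" else "personal"
  scenario_id <- if (origin == "scenario") state$scenario_queue[1L] else NA
  state$current <- list(origin = origin, scenario_id = scenario_id,
                        situation = NULL, emotion = NULL,
                        automatic_thought = NULL, behavior = NULL,
                        steps = character())
  if (origin == "scenario") {
    state$scenario_queue <- state$scenario_queue[-1L]
  }
  state$phase <- "ask_situation"
  prompt <- if (origin == "scenario") {
    "What happened in this situation that would cause you distress?"
  } else {
    paste("Think of a day-to-day situation from your own life that caused",
          "you a negative emotion. What happened?")
  }
  say(state, prompt)
}

finalize_record <- function(state) {
  cur <- state$current
  n <- length(state$completed_records) + 1L
  rec <- thought_record(
    record_id = sprintf("%s-s%d-r%d", state$participant_id,
                        state$session_index, n),
    participant_id = state$participant_id,
    session_index = state$session_index, origin = cur$origin,
    scenario_id = if (cur$origin == "scenario") cur$scenario_id else NULL,
    situation = cur$situation, emotion = cur$emotion,
    automatic_thought = cur$automatic_thought, behavior = cur$behavior,
    downward_steps = cur$steps, created_at = state$clock
  )
  state$completed_records[[n]] <- rec
  state$current <- NULL
  state$phase <- "feedback"
  bundle <- compose_feedback(state$condition, state$completed_records,
                             reference = state$reference,
                             scorer = state$scorer, schemas = state$schemas)
  state$last_feedback <- bundle
  for (m in bundle$text_messages) state <- say(state, m)
  say(state, "Press [ok] to continue.")
}

enter_continue_prompt <- function(state) {
  state$phase <- "continue_prompt"
  if (state$session_index == 1L) {
    say(state, "Are you ready for the next scenario? [yes]")
  } else {
    say(state, "Would you like to complete another thought record? [yes/no]")
  }
}

enter_closing <- function(state) {
  state$phase <- "closing"
  say(state, paste("That completes this session. Thank you, and see you",
                   "next time!"))
}

#' Advance the dialogue by one user turn
#'
#' Free text is expected in the thought-record phases (situation, emotion,
#' thought, behavior, downward arrow); enumerated button tokens everywhere
#' else. Empty or whitespace-only free text, and unknown button tokens,
#' leave the state unchanged and return a re-prompt message.
#'
#' @param state A `dialogue_state` from [start_session()] / `advance()`.
#' @param user_input One user turn (string).
#' @return List with elements `state` and `messages`.
#' @export
advance <- function(state, user_input) {
  stopifnot(inherits(state, "dialogue_state"))
  if (!is.character(user_input) || length(user_input) != 1L) {
    stop("user_input must be a single string")
  }
  phase <- state$phase
  if (phase %in% FREE_TEXT_PHASES) {
    if (phase == "downward_arrow") return(downward_arrow_next(state, user_input))
    if (!nzchar(trimws(user_input))) {
      return(list(state = state,
                  messages = "I did not catch that -- could you put it into words for me?"))
    }
    state <- hear(state, user_input)
    slot <- switch(phase, ask_situation = "situation", ask_emotion = "emotion",
                   ask_thought = "automatic_thought", ask_behavior = "behavior")
    state$current[[slot]] <- user_input
    state <- switch(
      phase,
      ask_situation = {
        state$phase <- "ask_emotion"
        say(state, "How did you feel in that situation?")
      },
      ask_emotion = {
        state$phase <- "ask_thought"
        say(state, "What went through your mind? What did you think?")
      },
      ask_thought = {
        state$phase <- "ask_behavior"
        say(state, "And what did you do in response?")
      },
      ask_behavior = {
        state$phase <- "downward_arrow"
        state <- say(state, sprintf(
          'Let\'s look more closely at the thought "%s".',
          state$current$automatic_thought))
        state <- say(state, state$config$probe_question)
        say(state, sprintf('(Type your answer, or [%s] when you have reached the core of it.)',
                           state$config$stop_token))
      }
    )
    return(reply(state))
  }
  # button phases
  token <- tolower(trimws(user_input))
  reprompt <- function(msg) list(state = state, messages = msg)
  switch(
    phase,
    scenario_presentation = {
      if (token != "ready") return(reprompt("Please press [ready] to continue."))
      state <- hear(state, token)
      state <- begin_record(state)
      reply(state)
    },
    feedback = {
      if (token != "ok") return(reprompt("Please press [ok] to continue."))
      state <- hear(state, token)
      n <- length(state$completed_records)
      if (state$session_index == 1L && n >= 2L) {
        state <- enter_closing(state)
      } else {
        state <- enter_continue_prompt(state)
      }
      reply(state)
    },
    continue_prompt = {
      n <- length(state$completed_records)
      if (state$session_index == 1L) {
        if (token != "yes") {
          return(reprompt(
            "The practice session has one more scenario -- please press [yes] when ready."))
        }
        state <- hear(state, token)
        state <- enter_scenario_presentation(state)
        return(reply(state))
      }
      if (token == "yes") {
        state <- hear(state, token)
        state <- begin_record(state)
        return(reply(state))
      }
      if (token == "no") {
        if (n < 1L) return(reprompt("Please complete at least one thought record first."))
        state <- hear(state, token)
        state <- enter_closing(state)
        return(reply(state))
      }
      reprompt("Please answer [yes] or [no].")
    },
    closing = reprompt("This session is over. Thank you!"),
    stop("internal error: unhandled phase ", phase)
  )
}

#' Downward-arrow loop step
#'
#' Appends a non-terminal answer as the next downward-arrow step and
#' re-issues the probe question about the latest thought. The loop ends on
#' the stop token, or is forcibly terminated when the chain has reached the
#' configured maximum depth (a safety bound; further inputs are not
#' appended).
#'
#' @param state A `dialogue_state` in phase `downward_arrow`.
#' @param user_input Free text (next step) or the stop token.
#' @return List with elements `state` and `messages`.
#' @export
downward_arrow_next <- function(state, user_input) {
  stopifnot(inherits(state, "dialogue_state"),
            identical(state$phase, "downward_arrow"))
  if (!nzchar(trimws(user_input))) {
    return(list(state = state,
                messages = "I did not catch that -- could you put it into words for me?"))
  }
  token <- tolower(trimws(user_input))
  at_limit <- length(state$current$steps) >= state$config$max_depth
  if (token == state$config$stop_token || at_limit) {
    state <- hear(state, user_input)
    if (at_limit && token != state$config$stop_token) {
      state <- say(state, "You have dug very deep -- let's stop the arrow here.")
    }
    state <- finalize_record(state)
    return(reply(state))
  }
  state <- hear(state, user_input)
  state$current$steps <- c(state$current$steps, user_input)
  state <- say(state, sprintf('And if "%s" were true -- %s',
                              user_input,
                              tolower_first(state$config$probe_question)))
  reply(state)
}

tolower_first <- function(x) {
  paste0(tolower(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Drive a session to completion with a scripted input sequence
#'
#' Feeds each element of `inputs` to [advance()] in order. Used for replay
#' testing and by the synthetic-participant simulator.
#'
#' @param state A `dialogue_state` (fresh from [start_session()]).
#' @param inputs Character vector of user turns.
#' @return The final `dialogue_state`.
#' @export
run_script <- function(state, inputs) {
  for (x in inputs) {
    state <- advance(state, x)$state
  }
  state
}

#' Export a session transcript as JSON Lines
#'
#' One event per line with fields `role`, `phase`, `text`, `t` (logical
#' clock).
#'
#' @param state A `dialogue_state`.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of JSON lines, or `path` invisibly.
#' @export
transcript_to_jsonl <- function(state, path = NULL) {
  stopifnot(inherits(state, "dialogue_state"))
  lines <- vapply(state$transcript, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE))
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.dialogue_state <- function(x, ...) {
  cat(sprintf("<dialogue_state> session %d, condition %s, phase %s\n",
              x$session_index, x$condition, x$phase))
  cat(sprintf("  completed records: %d; transcript events: %d\n",
              length(x$completed_records), length(x$transcript)))
  invisible(x)
}
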