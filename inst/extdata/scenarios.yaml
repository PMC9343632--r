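# Practice scenario library: 5 interpersonal + 5 achievement-related.
# Same content as default_scenario_library(); kept as a YAML example of the
# file format accepted by read_scenarios().
- id: int1
  category: interpersonal
  text: "An acquaintance walks past you on the street and does not wave back."
- id: int2
  category: interpersonal
  text: "A close friend cancels your plans for the third time in a row."
- id: int3
  category: interpersonal
  text: "At a party, the conversation stops when you join the group."
- id: int4
  category: interpersonal
  text: "Your partner seems distant and answers you in single words all evening."
- id: int5
  category: interpersonal
  text: "A family member criticizes how you handled a personal decision."
- id: ach1
  category: achievement
  text: "You are let go from your new job for not meeting your quota."
- id: ach2
  category: achievement
  text: "You receive a failing grade on an exam you studied hard for."
- id: ach3
  category: achievement
  text: "Your project proposal is rejected in front of the whole team."
- id: ach4
  category: achievement
  text: "You miss an important deadline despite working late all week."
- id: ach5
  category: achievement
  text: "A colleague hired after you is promoted ahead of you."
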