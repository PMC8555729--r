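{
  "_comment": "Edit the left-hand names to match the deposited CSV's columns; the right-hand names are the schema polarmeta expects. Entries whose left-hand name is absent from the file are ignored.",
  "trials": {
    "subject": "participant_id",
    "domain": "topic",
    "text": "text_id",
    "direction": "true_direction",
    "interpretation": "rating",
    "confidence": "confidence"
  },
  "participants": {
    "subject": "participant_id",
    "domain": "topic",
    "prior_belief": "prior",
    "posterior_belief": "posterior"
  }
}
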