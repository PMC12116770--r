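# Default sentence-level context-exclusion rules.
#
# A trigger anywhere in a sentence excludes every lexicon mention in that
# sentence (sentence-scope exclusion).  Triggers are word-level patterns:
# single spaces compile to \s+ and each trigger is word-boundary anchored.
# Precedence when several rule classes apply: negation > question > goal >
# family_history (the label differs; the exclusion outcome is identical).
negation:
  - "no"
  - "not"
  - "denies"
  - "denied"
  - "without"
  - "negative for"
  - "absence of"
  - "intact"
# A sentence is a question when it ends with "?".
question_terminal: "?"
goal:
  - "goal"
  - "goals"
  - "plan to"
  - "will work on"
  - "objective:"
family_history:
  - "mother"
  - "father"
  - "brother"
  - "sister"
  - "family history"
  - "fh of"
  - "parent"
  - "parents"
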