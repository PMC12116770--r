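# Default five-domain cognitive-impairment lexicon.
#
# Pattern syntax is word-level ICU regex: a single space between tokens is
# compiled to \s+, and each entry is wrapped in word boundaries, so patterns
# match across double spaces and never inside larger words.  Matching is
# case-insensitive.  `example` is a canonical surface phrase matched by the
# entry (used by the synthetic-note generator and in tests).
#
# Domain notes: social cognition is excluded (rarely documented in notes);
# visual learning is merged into verbal_learning_memory because the two
# domains' key terms overlap heavily in free text.  Five domains remain.
version: "1.0"
case_sensitive: false
entries:
  # --- Attention and vigilance -------------------------------------------
  - domain: attention_vigilance
    category: reduced attention
    patterns:
      - "(?:reduced|decreased|diminished|impaired) attention"
      - "attention (?:deficit|deficits|is reduced)"
    example: "reduced attention"
  - domain: attention_vigilance
    category: poor concentration
    patterns:
      - "(?:poor|impaired|decreased) concentration"
      - "(?:difficulty|difficulties|trouble) concentrating"
    example: "poor concentration"
  - domain: attention_vigilance
    category: difficulty understanding
    patterns:
      - "(?:difficulty|difficulties|trouble) understanding"
    example: "difficulty understanding"
  - domain: attention_vigilance
    category: difficulty staying focused
    patterns:
      - "(?:difficulty|difficulties|trouble) staying focused"
      - "unable to stay focused"
    example: "difficulty staying focused"

  # --- Reasoning and problem solving -------------------------------------
  # "insight and judgment" is also a routine mental-status-exam heading, so
  # by default it only counts when the sentence carries an impairment
  # qualifier (impaired/poor/limited/fair/...); see compile_lexicon().
  - domain: reasoning_problem_solving
    category: insight and judgment
    patterns:
      - "insight and judgment"
      - "judgment and insight"
    example: "insight and judgment"
    requires_qualifier: true
  - domain: reasoning_problem_solving
    category: learning new technology
    patterns:
      - "(?:learning|using|difficulty with) new technolog(?:y|ies)"
    example: "learning new technology"
  - domain: reasoning_problem_solving
    category: difficulty learning
    patterns:
      - "(?:difficulty|difficulties|trouble) learning"
    example: "difficulty learning"
  - domain: reasoning_problem_solving
    category: handling changes
    patterns:
      - "(?:difficulty|difficulties|trouble) handling changes"
      - "struggles to handle changes"
    example: "difficulty handling changes"
  - domain: reasoning_problem_solving
    category: manage bills money
    patterns:
      - "(?:unable|struggles|difficulty|difficulties|trouble) (?:to )?manag(?:e|ing) (?:bills|money|finances)"
    example: "difficulty managing bills"
  - domain: reasoning_problem_solving
    category: planning
    patterns:
      - "(?:poor|impaired) planning"
      - "(?:difficulty|difficulties|trouble) (?:with )?planning"
    example: "poor planning"
  - domain: reasoning_problem_solving
    category: difficulty problem solving
    patterns:
      - "(?:difficulty|difficulties|trouble) (?:with )?problem solving"
      - "unable to solve problems"
    example: "difficulty with problem solving"
  - domain: reasoning_problem_solving
    category: difficulties with concrete thinking
    patterns:
      - "(?:difficulty|difficulties) with concrete thinking"
      - "concrete thinking is impaired"
    example: "difficulties with concrete thinking"

  # --- Speed of processing ------------------------------------------------
  - domain: speed_of_processing
    category: poverty of thought
    patterns:
      - "poverty of thought"
    example: "poverty of thought"
  - domain: speed_of_processing
    category: thought blocking
    patterns:
      - "thought blocking"
      - "thought-blocking"
    example: "thought blocking"
  - domain: speed_of_processing
    category: participate in conversation
    patterns:
      - "(?:unable|struggles|difficulty|difficulties|trouble) (?:to )?participat(?:e|ing) in conversations?"
    example: "difficulty participating in conversation"
  - domain: speed_of_processing
    category: slow thinking
    patterns:
      - "slow(?:ed)? thinking"
      - "thinking is slow(?:ed)?"
    example: "slowed thinking"
  - domain: speed_of_processing
    category: difficulty integrating thoughts, feelings, and behavior
    patterns:
      - "(?:difficulty|difficulties) integrating thoughts"
    example: "difficulty integrating thoughts, feelings, and behavior"
  - domain: speed_of_processing
    category: ability to perform tasks
    patterns:
      - "(?:unable|impaired ability|limited ability) to perform tasks"
      - "cannot perform tasks"
    example: "impaired ability to perform tasks"
  - domain: speed_of_processing
    category: unable to do things quickly
    patterns:
      - "(?:unable|inability) to do things quickly"
      - "cannot do things quickly"
    example: "unable to do things quickly"

  # --- Verbal learning and memory ----------------------------------------
  - domain: verbal_learning_memory
    category: difficulty expressing themselves
    patterns:
      - "(?:difficulty|difficulties|trouble) expressing (?:himself|herself|themselves|thoughts)"
    example: "difficulty expressing themselves"
  - domain: verbal_learning_memory
    category: hindered speech
    patterns:
      - "(?:hindered|halting|impoverished) speech"
    example: "hindered speech"
  - domain: verbal_learning_memory
    category: limited vocabulary
    patterns:
      - "limited vocabulary"
    example: "limited vocabulary"
  - domain: verbal_learning_memory
    category: follow conversation
    patterns:
      - "(?:unable|struggles|difficulty|difficulties|trouble) (?:to )?follow(?:ing)? (?:a |the )?conversations?"
    example: "difficulty following a conversation"
  - domain: verbal_learning_memory
    category: remembering what they are going to say
    patterns:
      - "(?:forgets|difficulty remembering|cannot remember) what (?:he|she|they) (?:is|are|was|were) going to say"
    example: "difficulty remembering what they are going to say"

  # --- Working memory -----------------------------------------------------
  - domain: working_memory
    category: poor memory
    patterns:
      - "(?:poor|impaired|bad) memory"
    example: "poor memory"
  - domain: working_memory
    category: remembering how to get to places
    patterns:
      - "(?:difficulty|difficulties|trouble) remembering how to get (?:to )?places"
      - "forgets how to get to places"
    example: "difficulty remembering how to get to places"
  - domain: working_memory
    category: difficulties remembering things
    patterns:
      - "(?:difficulty|difficulties|trouble) remembering things"
    example: "difficulties remembering things"
  - domain: working_memory
    category: remembering names of people
    patterns:
      - "(?:difficulty|difficulties|trouble) remembering (?:the )?names of people"
      - "cannot remember names"
    example: "difficulty remembering names of people"
  - domain: working_memory
    category: remembering where they put things
    patterns:
      - "(?:difficulty|difficulties|trouble) remembering where (?:he|she|they) put things"
      - "forgets where (?:he|she|they) puts? things"
    example: "difficulty remembering where they put things"
  - domain: working_memory
    category: remembering chores and responsibilities
    patterns:
      - "(?:difficulty|difficulties|trouble|forgets) remembering chores and responsibilities"
    example: "difficulty remembering chores and responsibilities"
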