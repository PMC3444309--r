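# Representative CTX abstraction ruleset.
#
# Grammar: a top-level `parameters:` mapping of named numeric thresholds and
# a `rules:` list. Each rule has `id`, `when` (conjunction of atoms) and
# `then` (term, polarity, group). Atom forms:
#   - {status: <term_id>, polarity: present|absent}   status-check
#   - {attribute: <name>, op: "<"|"<="|"="|">="|">", value: <number|parameter>}
#   - {class: <term_id>}                              class-membership
#
# "Childhood-onset" is read as onset strictly before 16 years (covers
# pediatric-onset classes); "chronic" as duration of at least 4 weeks (the
# standard chronic-diarrhea definition). Both are parameters, not constants.

parameters:
  childhood_onset_max_age: 16.0
  chronic_min_duration: 4.0

rules:
  - id: cocd-presence
    when:
      - {status: Diarrhea, polarity: present}
      - {attribute: diarrhea_onset_age, op: "<", value: childhood_onset_max_age}
      - {attribute: diarrhea_duration_weeks, op: ">=", value: chronic_min_duration}
    then: {term: ChildhoodOnsetChronicDiarrhea, polarity: present, group: extra-neurological}

  # Downward absence for a defined composite concept: a patient asserted not
  # to have diarrhea at all cannot have its childhood-onset chronic form.
  - id: cocd-absence
    when:
      - {status: Diarrhea, polarity: absent}
    then: {term: ChildhoodOnsetChronicDiarrhea, polarity: absent, group: extra-neurological}

  # Property-group links: one derived marker assertion per manifestation
  # group, attached when any presence assertion falls under the group class.
  - id: link-neurological
    when:
      - {class: AbnormalityOfTheNervousSystem}
    then: {term: AbnormalityOfTheNervousSystem, polarity: present, group: neurological}

  - id: link-extra-neurological
    when:
      - {class: ExtraNeurologicalAbnormality}
    then: {term: ExtraNeurologicalAbnormality, polarity: present, group: extra-neurological}

  - id: link-diagnostic
    when:
      - {class: AbnormalDiagnosticFinding}
    then: {term: AbnormalDiagnosticFinding, polarity: present, group: diagnostic-study}
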