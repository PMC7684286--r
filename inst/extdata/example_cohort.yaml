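# Minimal synthetic cohort design: two substituted deaf birds and two
# deaf controls (all fields not listed take the bird_params defaults).
birds:
  - bird_id: ex_subs_high
    group: subs
    target_side: high
    response_per_day: 0.19
  - bird_id: ex_subs_low
    group: subs
    target_side: low
    response_per_day: 0.19
  - bird_id: ex_unsubs_1
    group: unsubs
    target_side: none
  - bird_id: ex_unsubs_2
    group: unsubs
    target_side: none
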