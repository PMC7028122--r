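participant_id: participant_id
faces_run1: faces_run1
faces_run2: faces_run2
search_run1: search_run1
search_run2: search_run2
acuity_logmar: acuity_logmar
contrast_logcs: contrast_logcs
digit_span: digit_span
usability_faces: usability_faces
usability_search: usability_search

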