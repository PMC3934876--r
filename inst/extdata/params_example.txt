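# Example model-parameter file: key = value, '#' starts a comment.
# Omitted keys keep their defaults (shown here). Pass via
# pipeline_config(params_file = ...) or consmsa.R align --params.

# five-state pair HMM
hmm_init_match     = 0.6814757
hmm_init_short     = 0.1291759622
hmm_init_long      = 0.0302861878
hmm_gap_open_short = 0.0119511066
hmm_gap_open_long  = 0.008008334786
hmm_gap_ext_short  = 0.3965826333
hmm_gap_ext_long   = 0.8988758326

# partition function (half-bit substitution score scale)
pf_beta     = 1.0
pf_gap_open = -4.5
pf_gap_ext  = -0.25
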