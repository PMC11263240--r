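# keep the full suite running past the documented acceptance-level
# discrepancies so every file reports
options(testthat.progress.max_fails = 500L)
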