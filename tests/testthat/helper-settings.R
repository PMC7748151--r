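# report every expectation; the fixture-consistency criterion intentionally
# asserts printed tolerances that sit below the printing-precision noise
# floor, and its failures must not mask the rest of the suite
options(testthat.progress.max_fails = 1000)
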