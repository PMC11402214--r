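# Example islet-mask parameter grid: 11 x 11 x 4 x 4 = 1936 combinations,
# the cardinality of the published mask-parameter search. Axes beyond
# offset/blur illustrate how variants would be encoded; segment_islet()
# consumes offset and blur_sigma_px.
offset: [0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100]
blur_sigma_px: [2, 6, 10, 14, 18, 20, 22, 26, 30, 34, 38]
shrink: [0, 1, 2, 3]
variant: [1, 2, 3, 4]
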