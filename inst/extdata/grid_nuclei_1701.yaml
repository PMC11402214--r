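# Example nucleus-detector grid: 7 x 9 x 27 = 1701 combinations, the
# cardinality of the published nucleus-parameter search.
blur_sigma_px: [3, 5, 7, 9, 11, 13, 15]
peak_threshold: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
overlap_threshold: [0.04, 0.07, 0.1, 0.14, 0.17, 0.2, 0.24, 0.27, 0.3, 0.34,
                    0.37, 0.4, 0.44, 0.47, 0.5, 0.54, 0.57, 0.6, 0.64, 0.67,
                    0.7, 0.74, 0.77, 0.8, 0.84, 0.87, 0.9]
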