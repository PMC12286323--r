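Reference worked-example values for the two reported pipeline
configurations on the recorded reading-comprehension data:

  strategy 1, TotalHb IMF4 trials (1300 segments, 8 symbols)
  strategy 3, DeoxyHb IMF3 trials (1300 segments, 8 symbols)

reference_strategy{1,3}_confusion.csv : per-run test confusion counts
reference_strategy{1,3}_metrics.csv   : per-run PAM and its constituents
                                        (percent columns as printed; AUC,
                                        J, FM as 2-decimal fractions)
reference_precision.csv               : per-run precision values

These tables are inputs to validation: the metric columns are recomputed
from the confusion counts by the package and compared at the precision
the values were published with. Note: strategy 3 run 4 SP (77.67) is
inconsistent with its own confusion counts (23/30 = 76.67); the
recomputation asserts the counts-derived value.
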