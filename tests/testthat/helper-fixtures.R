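# Small count-table constructors used across test files.

# Collapse-free 2AFC table from the four type-I outcome counts ("S2" is the
# signal class); all responses at the lowest confidence level, K = 2.
new_counts_toy <- function(hit, miss, fa, cr) {
  metacov:::new_counts_table(
    nR_S1 = c(0, cr, fa, 0),
    nR_S2 = c(0, miss, hit, 0),
    n_levels = 2
  )
}

# Counts table whose correct/incorrect confidence distributions (ascending
# levels) are exactly as given: correct trials as stim S1 / resp S1,
# incorrect as stim S1 / resp S2.
counts_from_conf_acc <- function(correct, incorrect) {
  stopifnot(length(correct) == length(incorrect))
  metacov:::new_counts_table(
    nR_S1 = c(rev(correct), incorrect),
    nR_S2 = rep(0, 2 * length(correct)),
    n_levels = length(correct)
  )
}
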