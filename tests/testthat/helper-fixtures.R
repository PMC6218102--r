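# Shared desk-scale objects for the test suite.

# RQ5427-like design: 8 retained samples (plus the excluded month-2 one
# in the synthetic default), S+ mid-range, tagged pool 1.664e8.
desk_design <- function(J = 8, S_plus = 1.5e4, M_ss_plus = 1.664e8,
                        first_month = 7, gap = 5) {
  experiment_design(seq(first_month, by = gap, length.out = J),
                    S_plus, M_ss_plus)
}

# abundance_matrix straight from a fraction matrix (integer-count
# compatible S_plus required)
ab_from_fractions <- function(f, S_plus = 100,
                              t_months = seq(10, by = 8,
                                             length.out = ncol(f)),
                              M_ss_plus = 1e6) {
  counts <- round(f * S_plus)
  stopifnot(max(abs(counts - f * S_plus)) < 1e-9)
  design <- experiment_design(t_months, S_plus, M_ss_plus)
  cloneburst:::new_abundance_matrix(counts, counts / S_plus, design)
}

expect_rel_equal <- function(x, y, rel) {
  expect_lt(abs(x - y) / abs(y), rel)
}
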