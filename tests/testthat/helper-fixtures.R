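# Shared fixtures: reference tissue matrices and composed optical elements.

gbm_M <- tissue_preset("gbm")
non_gbm_M <- tissue_preset("non_gbm")

# depolarizer . retarder . diattenuator with known ground-truth parameters
composed_sample <- function(delta_dep, delta_ret = 0, theta = 0,
                            d1 = 0, d2 = 0, backscatter = FALSE) {
  make_depolarizer(delta_dep, backscatter) %*%
    make_linear_retarder(delta_ret, theta) %*%
    make_diattenuator(d1, d2)
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
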