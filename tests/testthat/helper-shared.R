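# Expensive shared fixtures, built lazily once per test run and cached.

.shared <- new.env(parent = emptyenv())

shared_get <- function(name, builder) {
  if (is.null(.shared[[name]])) .shared[[name]] <- builder()
  .shared[[name]]
}

# large correctly-specified Case 1 sample with joint and y-only fits
shared_case1_big <- function() {
  shared_get("case1_big", function() {
    d <- generate_case("case1", 5000L, seed = 1301L)
    fit_b <- fit_gmm(d, use_auxiliary = TRUE, control = fit_control(seed = 1302L))
    fit_y <- fit_gmm(d, use_auxiliary = FALSE, control = fit_control(seed = 1303L))
    list(data = d, fit_b = fit_b, fit_y = fit_y,
         mats_b = info_matrices(fit_b, d),
         mats_y = info_matrices(fit_y, aux_dataset(d$y)))
  })
}

# moderate Case 1 sample for criterion/reduction identities
shared_case1_mid <- function() {
  shared_get("case1_mid", function() {
    d <- generate_case("case1", 200L, seed = 2201L)
    fit_b <- fit_gmm(d, use_auxiliary = TRUE, control = fit_control(seed = 2202L))
    fit_y <- fit_gmm(d, use_auxiliary = FALSE, control = fit_control(seed = 2203L))
    base <- aux_dataset(d$y)
    list(data = d, base = base, fit_b = fit_b, fit_y = fit_y,
         mats_b = info_matrices(fit_b, d),
         mats_y = info_matrices(fit_y, base))
  })
}
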