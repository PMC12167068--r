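# Shared small fixtures, built once per test run.

tiny_tax <- generate_taxonomy(n_conditions = 22, n_categories = 11,
                              n_high_risk = 4, seed = 42)

small_tax <- generate_taxonomy(n_conditions = 44, n_categories = 11,
                               n_high_risk = 6, seed = 7)

uniform_profile <- function(tax, n, noise_scale = 1, name = "DEV") {
  K <- length(tax$categories)
  domain_profile(name, rep(1 / K, K), n, noise_scale)
}

# A trained small world reused by model/prediction/calibration tests:
# uniform priors, low-ambiguity regime so the held-out top-7 accuracy
# comfortably exceeds the sensitivity targets the policy tests use.
small_world <- local({
  prof <- uniform_profile(small_tax, 1600, noise_scale = 0.45)
  cases <- generate_cases(small_tax, prof, d = 12, seed = 3)
  model <- train_classifier(
    subset_cases(cases, 1:1100), cases$info$true_condition[1:1100],
    new_classifier(small_tax, 12, d_meta = 12, seed = 1),
    loss_config(train_steps = 250, learning_rate = 0.1, seed = 2)
  )
  holdout <- subset_cases(cases, 1101:1600)
  list(tax = small_tax, cases = cases, model = model, holdout = holdout,
       holdout_labels = cases$info$true_condition[1101:1600])
})

make_diff <- function(conditions, confidences, raw = conditions) {
  data.frame(raw_label = raw, condition = conditions,
             confidence = confidences, stringsAsFactors = FALSE)
}
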