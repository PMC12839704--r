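# Shared fixtures. The expensive trained-model fixture is built once per test
# run and reused by every test that needs a fitted classifier.

case_demo <- list(sex = "woman", age = 45, bmi = 18.1)

make_page <- function(pixels) {
  structure(list(pixels = pixels, dpi = 150L, source_path = NA_character_,
                 text = NA_character_), class = "report_page")
}

# White RGB page with dark rectangles stamped at given 1-based row/col ranges.
blob_page <- function(h, w, blobs, gray = 0) {
  px <- array(1, dim = c(h, w, 3L))
  for (b in blobs) px[b$rows, b$cols, ] <- gray
  make_page(px)
}

clean_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- simulate_maneuver(maneuver_params())
      cache <<- render_report(m, case_demo)
    }
    cache
  }
})

cough_report_with_post_bd <- function() {
  m <- simulate_maneuver(maneuver_params())
  render_report(m, case_demo, include_post_bd = TRUE)$page
}

cough_report <- function(amplitude = 6, seed = 42, demo = case_demo) {
  pp <- maneuver_params(artifact = "cough",
                        artifact_params = list(amplitude = amplitude),
                        seed = seed)
  m <- inject_artifact(simulate_maneuver(pp), pp)
  render_report(m, demo)
}

# Scaled-down end-to-end experiment: 200 synthetic reports (clean vs
# strong-cough), the study's class prevalence, full augmentation, and a
# from-scratch fit of the compact network. Built lazily, cached for the run.
.trained_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.trained_env$fix)) return(.trained_env$fix)
  sim <- simulate_constructs(200, unacceptable_fraction = 79 / 224,
                             seed = 1234,
                             artifact_types = "cough",
                             artifact_params = list(amplitude = 6))
  sp <- split_dataset(sim$labels, split_spec(seed = 1234))
  fit <- train_classifier(
    build_classifier(seed = 7), sim$inputs, sim$labels,
    tc = train_config(max_epochs = 40, mini_batch = 16,
                      learning_rate = 3e-3, validation_patience = 20),
    ac = augment_config(),
    train_idx = sp$train, val_idx = sp$validation, seed = 1234)
  val_risk <- predict_risk(fit, sim$inputs[, , sp$validation])
  thr <- select_threshold(val_risk, sim$labels[sp$validation])
  .trained_env$fix <- list(sim = sim, split = sp, fit = fit,
                           threshold = thr$threshold)
  .trained_env$fix
}
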