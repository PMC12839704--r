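#' Generate a labelled synthetic spirometry report dataset
#'
#' Draws manoeuvre parameters and demographics at random, injects artifacts
#' into the unacceptable portion of the dataset, renders each manoeuvre as a
#' report page and (optionally) writes one PNG page plus a text-layer sidecar
#' per report, together with a manifest CSV. The default class split follows
#' the 79/224 unacceptable prevalence of primary-care training-course
#' spirometry audits; demographics are uniform over the normalization bounds
#' (age 10-84 years, BMI 15-54 kg/m2, sex Bernoulli(0.5)) with no claim of
#' population realism.
#'
#' The number of unacceptable reports is `round_half_up(n *
#' unacceptable_fraction)`; artifact types are drawn uniformly from
#' `artifact_types`. With the same `seed` the manifest is byte-identical
#' across runs.
#'
#' @param n Number of reports (>= 2).
#' @param unacceptable_fraction Proportion of unacceptable reports in (0, 1).
#' @param seed Integer seed; all randomness derives from it.
#' @param out_dir Output directory; if `NULL` nothing is written and the
#'   rendered reports are returned in memory.
#' @param post_bd_prob Probability that a page carries a red
#'   post-bronchodilator overlay.
#' @param artifact_types Artifact families to draw from for unacceptable
#'   reports.
#' @param artifact_params Named list of overrides forwarded to
#'   [inject_artifact()] (e.g. `list(amplitude = 6)` for strong coughs).
#' @param layout Page layout, see [default_layout()].
#' @param transform Optional function applied to each rendered report before
#'   it is stored in the in-memory result (e.g. to reduce a full page to a
#'   construct); ignored when `out_dir` is given.
#' @return A list with `manifest` (data.frame: path, label, sex, age, bmi,
#'   artifact) and, when `out_dir` is `NULL`, `reports` (list of
#'   [render_report()] objects, or of `transform` results).
#' @export
generate_dataset <- function(n, unacceptable_fraction = 79 / 224, seed = 1L,
                             out_dir = NULL, post_bd_prob = 0.3,
                             artifact_types = c("cough", "early_termination",
                                                "submaximal", "extra_breath"),
                             artifact_params = list(),
                             layout = default_layout(), transform = NULL) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (unacceptable_fraction <= 0 || unacceptable_fraction >= 1)
    stop("unacceptable_fraction must be strictly between 0 and 1",
         call. = FALSE)
  n_unacc <- round_half_up(n * unacceptable_fraction)
  if (n_unacc == 0 || n_unacc == n)
    warning("degenerate class split: all reports belong to one class")

  set.seed(as.integer(seed))
  labels <- sample(c(rep("unacceptable", n_unacc),
                     rep("acceptable", n - n_unacc)))
  draws <- data.frame(
    fvc = runif(n, 2.5, 5.5), pef = runif(n, 5, 10),
    rise = runif(n, 0.08, 0.15), tau = runif(n, 0.4, 0.8),
    sex = ifelse(runif(n) < 0.5, "man", "woman"),
    age = sample(10:84, n, replace = TRUE),
    bmi = round(runif(n, 15, 54), 1),
    post_bd = runif(n) < post_bd_prob,
    artifact = sample(artifact_types, n, replace = TRUE),
    aseed = sample.int(.Machine$integer.max - 1L, n))

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[i, ]
    art <- if (labels[i] == "unacceptable") d$artifact else "none"
    pp <- maneuver_params(fvc = d$fvc, pef = d$pef, rise_time = d$rise,
                          decay_tau = d$tau, artifact = art,
                          artifact_params = artifact_params, seed = d$aseed)
    m <- simulate_maneuver(pp)
    if (art != "none") m <- inject_artifact(m, pp)
    demo <- list(sex = d$sex, age = d$age, bmi = d$bmi)
    rep_i <- render_report(m, demo, include_post_bd = d$post_bd,
                           layout = layout)
    path <- if (is.null(out_dir)) sprintf("report_%04d.png", i) else
      file.path(out_dir, sprintf("report_%04d.png", i))
    if (!is.null(out_dir)) {
      png::writePNG(rep_i$page$pixels, path)
      writeLines(rep_i$text, sub("\\.png$", ".txt", path))
      rep_i$page$source_path <- path
    } else {
      reports[[i]] <- if (is.null(transform)) rep_i else transform(rep_i)
    }
    rows[[i]] <- data.frame(path = path, label = labels[i], sex = d$sex,
                            age = d$age, bmi = d$bmi, artifact = art)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    list(manifest = manifest)
  } else {
    list(manifest = manifest, reports = reports)
  }
}

#' Generate labelled graphical constructs directly
#'
#' Streams [generate_dataset()] through the construct pipeline one report at
#' a time, so that study-scale datasets fit in memory: each rendered page is
#' reduced immediately to its 224x224 network input, its demographic frame
#' grays and (for artifacts) the annotation box mapped into network-input
#' coordinates.
#'
#' @inheritParams generate_dataset
#' @return A list: `inputs` (224 x 224 x n array on `[0, 255]`), `labels`,
#'   `manifest`, `annotations` (per-report construct-coordinate boxes or
#'   `NULL`), `frame_grays` (3 x n matrix).
#' @export
simulate_constructs <- function(n, unacceptable_fraction = 79 / 224,
                                seed = 1L, post_bd_prob = 0.3,
                                artifact_types = c("cough",
                                                   "early_termination",
                                                   "submaximal",
                                                   "extra_breath"),
                                artifact_params = list(),
                                layout = default_layout()) {
  res <- generate_dataset(
    n, unacceptable_fraction, seed, out_dir = NULL,
    post_bd_prob = post_bd_prob, artifact_types = artifact_types,
    artifact_params = artifact_params, layout = layout,
    transform = function(r) {
      gc <- build_construct(r$page, r$demographics)
      list(input = gc$network_input[, , 1],
           frame_grays = gc$frame_grays,
           annotation = if (is.null(r$artifact_annotation)) NULL else
             map_page_box_to_construct(gc, r$artifact_annotation),
           label = r$label, artifact = r$artifact)
    })
  X <- array(0, dim = c(224L, 224L, n))
  for (i in seq_len(n)) X[, , i] <- res$reports[[i]]$input
  list(inputs = X, labels = res$manifest$label, manifest = res$manifest,
       annotations = lapply(res$reports, `[[`, "annotation"),
       frame_grays = vapply(res$reports, `[[`, numeric(3), "frame_grays"))
}
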