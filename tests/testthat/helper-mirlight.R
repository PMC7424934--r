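# Shared fixtures: decompositions and model responses are expensive, so they
# are computed once per test run and cached across test files.

.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(name, mirrored = FALSE, params = mir_params()) {
  key <- paste0("fit:", name, ":", mirrored, ":", params_hash(params))
  if (is.null(.fit_cache[[key]])) {
    .fit_cache[[key]] <- mir_decompose(mir_stimulus(name, mirrored), params)
  }
  .fit_cache[[key]]
}

cached_response <- function(model, name, params = mir_params()) {
  key <- paste0("resp:", model, ":", name)
  if (is.null(.fit_cache[[key]])) {
    .fit_cache[[key]] <- if (model == "mir") {
      fit <- cached_fit(name, params = params)
      structure(list(model = "mir", stimulus = fit$stimulus,
                     map = fit$reflectance, scale = diff(range(fit$reflectance))),
                class = "mir_response")
    } else {
      run_model(model, name, params = params)
    }
  }
  .fit_cache[[key]]
}

cached_verdicts <- function(model, names, params = mir_params()) {
  res <- lapply(names, function(nm)
    illusion_difference(cached_response(model, nm, params)))
  names(res) <- names
  res
}

# small random luminance grid with a few flat patches (so features exist)
random_grid <- function(H, W, seed) {
  set.seed(seed)
  matrix(10^runif(H * W, 1, 2), H, W)
}
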