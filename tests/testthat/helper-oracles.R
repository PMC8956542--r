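# Oracle models for pipeline tests: exact-HU lookups on noise-free
# phantoms, replayed through the predict_* generics.

# classifier oracle: positive iff the slice contains a heart-valued pixel
make_oracle_bundle <- function(cfg) {
  ws <- window_setting()
  heart_vals <- window_intensity(cfg$structure_hu, ws)
  cls <- structure(list(heart_vals = heart_vals), class = "hc_oracle_cls")
  ax <- structure(list(heart_vals = heart_vals,
                       config = list(structures = c("WH", "LV", "RV",
                                                    "LA", "RA"))),
                  class = "hc_oracle_ax")
  ones <- structure(list(config = list(structures = "WH")),
                    class = "hc_oracle_ones")
  list(classifier = cls, axial = ax, coronal = ones, sagittal = ones)
}

register_oracles <- function() {
  env <- asNamespace("heartcascade")
  registerS3method("predict_slice", "hc_oracle_cls", function(net, image) {
    as.numeric(any(outer(as.vector(image), net$heart_vals,
                         function(a, b) abs(a - b) < 1e-9)))
  }, envir = env)
  registerS3method("predict_segmenter", "hc_oracle_ax",
                   function(net, image) {
    S <- net$config$structures
    out <- array(0, dim = c(dim(image), length(S)),
                 dimnames = list(NULL, NULL, S))
    # WH = any heart value; chambers = their own value
    out[, , "WH"] <- outer(as.vector(image), net$heart_vals,
                           function(a, b) abs(a - b) < 1e-9) |>
      matrix(nrow = nrow(image) * ncol(image)) |> rowSums() |>
      pmin(1) |> matrix(nrow(image), ncol(image))
    for (s in c("LV", "RV", "LA", "RA")) {
      out[, , s] <- (abs(image - net$heart_vals[[s]]) < 1e-9) * 1
    }
    out
  }, envir = env)
  registerS3method("predict_segmenter", "hc_oracle_ones",
                   function(net, image) {
    array(1, dim = c(dim(image), 1))
  }, envir = env)
}

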