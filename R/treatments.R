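#' Treatment labels for the 2x2 temperature-by-feeding design
#'
#' The experimental design crosses two rearing temperatures (cold = 20
#' degrees C, warm = 30 degrees C) with two feeding frequencies (continuous
#' = fed every morning, intermittent = fed every second morning). The four
#' combinations are keyed `conti_20`, `inter_20`, `conti_30`, `inter_30`
#' throughout the package.
#'
#' @return Character vector of the four treatment keys, in canonical order.
#' @export
treatment_keys <- function() {
  c("conti_20", "inter_20", "conti_30", "inter_30")
}

#' Build a treatment key from its temperature and feeding labels
#'
#' @param temperature `"cold"` or `"warm"` (20 vs 30 degrees C).
#' @param food `"continuous"` or `"intermittent"`.
#' @return Treatment key such as `"conti_20"`.
#' @export
treatment_key <- function(temperature, food) {
  temperature <- match.arg(temperature, c("cold", "warm"), several.ok = FALSE)
  food <- match.arg(food, c("continuous", "intermittent"), several.ok = FALSE)
  paste0(ifelse(food == "continuous", "conti", "inter"),
         "_", ifelse(temperature == "cold", "20", "30"))
}

#' Split treatment keys into temperature and feeding labels
#'
#' @param key Character vector of treatment keys.
#' @return A data.frame with columns `treatment`, `temperature`
#'   (`cold`/`warm`) and `food` (`continuous`/`intermittent`).
#' @export
treatment_labels <- function(key) {
  stopifnot(all(key %in% treatment_keys()))
  data.frame(
    treatment = key,
    temperature = ifelse(grepl("_30$", key), "warm", "cold"),
    food = ifelse(grepl("^conti", key), "continuous", "intermittent"),
    stringsAsFactors = FALSE
  )
}
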