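.defaultConfig <- function() {
    list(
        io = list(scanWidthMm = 4.5),
        preprocess = list(equalizeBins = 256L, lowpassSigmaPx = 2),
        shadow = list(windowPx = 25L, k = 0.9, minObjectPx = 50L,
                      dilatePx = 1L),
        segment = list(bins = 256L),
        roi = list(blackLevel = 0.02, minDiscAreaMm2 = 0.8))
}

#' Pipeline configuration
#'
#' Returns the nested configuration list for the measurement pipeline,
#' optionally overriding individual keys. Unknown sections or keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' Sections and defaults:
#' \describe{
#'   \item{io}{`scanWidthMm = 4.5` — physical scan width (mm).}
#'   \item{preprocess}{`equalizeBins = 256`, `lowpassSigmaPx = 2` —
#'     equalization bins and Gaussian sigma (px) for the shadow-stage
#'     preprocessing.}
#'   \item{shadow}{`windowPx = 25`, `k = 0.9`, `minObjectPx = 50`,
#'     `dilatePx = 1` — local-threshold window, offset multiplier,
#'     small-object cutoff and safety dilation.}
#'   \item{segment}{`bins = 256` — modified-Otsu histogram bins.}
#'   \item{roi}{`blackLevel = 0.02`, `minDiscAreaMm2 = 0.8` — disc
#'     detection black level and minimum disc area.}
#' }
#'
#' @param ... named lists per section, e.g.
#'   `ppcmvConfig(shadow = list(k = 0.3))`.
#' @return nested named list.
#' @export
ppcmvConfig <- function(...) {
    cfg <- .defaultConfig()
    over <- list(...)
    if (length(over) == 0L) return(cfg)
    if (is.null(names(over)) || any(names(over) == ""))
        stop("configuration overrides must be named sections")
    for (sec in names(over)) {
        if (!sec %in% names(cfg))
            stop("unknown configuration section '", sec, "'")
        v <- over[[sec]]
        if (!is.list(v)) stop("section '", sec, "' must be a named list")
        bad <- setdiff(names(v), names(cfg[[sec]]))
        if (length(bad))
            stop("unknown key(s) in section '", sec, "': ",
                 paste(bad, collapse = ", "))
        cfg[[sec]][names(v)] <- v
    }
    cfg
}
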