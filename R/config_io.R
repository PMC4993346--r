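# YAML configuration loading and config fingerprinting.

#' Load a model configuration from a YAML file
#'
#' The file may contain blocks `phases`, `fate`, `apoptosis`, `aux`, `run`
#' and `genotype_modifiers`; any missing block or field falls back to the
#' documented default (in particular, an omitted `apoptosis` block means the
#' all-zero "clean" model). An annotated default file ships with the package
#' (see the example). Named genotype modifiers are attached as the
#' `"modifiers"` attribute of the returned configuration.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `niche_config`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "default_config.yaml",
#'                                package = "nichegrowth"))
#' transit_time(cfg, "I")
load_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_config(sprintf("YAML parse failure in %s: %s",
                                                           path, conditionMessage(e))))
  if (!is.list(raw)) abort_config("config file must contain a YAML mapping")
  known <- c("phases", "fate", "apoptosis", "aux", "run", "genotype_modifiers")
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort_config(sprintf("unknown config block(s): %s",
                                        paste(bad, collapse = ", ")))

  take <- function(block, fn, who) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    if (length(bad)) abort_config(sprintf("unknown key(s) in '%s': %s",
                                          who, paste(bad, collapse = ", ")))
    do.call(fn, args)
  }
  phases <- take("phases", phase_durations, "phases")
  fate <- take("fate", fate_rule, "fate")
  apoptosis <- take("apoptosis", apoptosis_spec, "apoptosis")
  aux <- take("aux", auxiliary_spec, "aux")

  run <- raw$run
  if (is.null(run)) run <- list()
  run_ok <- c("t_start", "t_end", "initial_volume", "initial_age",
              "p_override", "erlang_m", "division_yield")
  bad <- setdiff(names(run), run_ok)
  if (length(bad)) abort_config(sprintf("unknown key(s) in 'run': %s",
                                        paste(bad, collapse = ", ")))
  cfg <- do.call(model_config,
                 c(list(phases = phases, fate = fate, apoptosis = apoptosis,
                        aux = aux), run))

  mods <- raw$genotype_modifiers
  if (!is.null(mods)) {
    mods <- lapply(mods, function(m) do.call(genotype_modifier, m))
    attr(cfg, "modifiers") <- mods
  }
  cfg
}

#' Fingerprint a configuration
#'
#' A short deterministic hash of every numeric parameter in a configuration,
#' recorded in trajectory metadata and run manifests so outputs can be tied
#' back to the exact parameter set that produced them.
#'
#' @param config A `niche_config`.
#' @return A hex string.
#' @export
config_fingerprint <- function(config) {
  validate_config(config)
  flat <- unlist(config[c("phases", "fate", "apoptosis", "aux")], use.names = TRUE)
  flat <- c(flat,
            t_start = config$t_start, t_end = config$t_end,
            initial_volume = config$initial_volume,
            initial_age = config$initial_age,
            p_override = ifelse(is.null(config$p_override), -1, config$p_override),
            erlang_m = config$erlang_m, division_yield = config$division_yield)
  txt <- paste(names(flat), format(flat, digits = 15), sep = "=", collapse = ";")
  # polynomial rolling hash mod 2^31 - 1 over the canonical parameter string
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
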