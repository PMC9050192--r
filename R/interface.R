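#' Default run configuration
#'
#' All model constants with their standard values: LIF neuron parameters
#' (V_th = -55 mV, V_rest = -75 mV, tau_m = 20 ms), plasticity parameters
#' (A+ = 0.925, A- = 0.1, tau+ = tau- = 20 ms, tau_e = 5 ms), style-reward
#' constants (gamma = 2, beta = 1), scoring constants (R_base = 50,
#' C_time = 3, L_collision = 40, L_help = 10), coding and training
#' settings. [load_config()] fills any YAML file against these defaults.
#'
#' @return a nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    neuron = list(v_threshold = -55, v_rest = -75, tau_m = 20,
                  membrane_resistance = 1, dt = 1),
    plasticity = list(a_plus = 0.925, a_minus = 0.1, tau_plus = 20,
                      tau_minus = 20, tau_e = 5, learning_rate = 0.1),
    coding = list(inhibition_strength = 0.1, input_gain = 20,
                  policy_input_gain = 60),
    network = list(window_length = 50),
    tom = list(gamma = 2, beta = 1),
    score = list(r_base = 50, c_time = 3, l_collision = 40, l_help = 10),
    training = list(episodes = 300, exploration_epsilon = 1.0,
                    epsilon_min = 0.05, epsilon_decay_frac = 0.5,
                    step_cap = 30),
    evaluation = list(episodes = 100),
    seed = 1
  ), class = "run_config")
}

.validate_config <- function(cfg) {
  with(cfg, {
    if (!(neuron$v_threshold > neuron$v_rest)) {
      .stopf("neuron: v_threshold must exceed v_rest")
    }
    if (neuron$tau_m <= 0 || neuron$dt <= 0) {
      .stopf("neuron: tau_m and dt must be positive")
    }
    if (plasticity$a_plus < 0 || plasticity$a_minus < 0) {
      .stopf("plasticity: amplitudes must be >= 0")
    }
    if (plasticity$tau_plus <= 0 || plasticity$tau_minus <= 0 ||
        plasticity$tau_e <= 0) {
      .stopf("plasticity: time constants must be positive")
    }
    if (coding$inhibition_strength < 0) {
      .stopf("coding: inhibition_strength must be >= 0")
    }
    if (network$window_length < 1) {
      .stopf("network: window_length must be >= 1")
    }
    if (training$exploration_epsilon < 0 || training$exploration_epsilon > 1) {
      .stopf("training: exploration_epsilon must lie in [0, 1]")
    }
    if (training$episodes < 0) .stopf("training: episodes must be >= 0")
    if (any(unlist(score) < 0)) .stopf("score: parameters must be >= 0")
  })
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial or empty) YAML file and merges it over the
#' [default_config()]. Unknown keys at either level and out-of-range values
#' are rejected with field-level messages.
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .stopf("config file '%s' does not exist", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) {
    for (section in names(user)) {
      if (!section %in% names(cfg)) {
        .stopf("unknown config section '%s'", section)
      }
      if (section == "seed") {
        cfg$seed <- user$seed
        next
      }
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]])) {
          .stopf("unknown config key '%s.%s'", section, key)
        }
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    }
  }
  .validate_config(structure(cfg, class = "run_config"))
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Stable hash of an R object: canonical JSON written to a temp file and
# md5-summed (tools::md5sum is the only digest facility in base R).
.hash_obj <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Build a reproducibility manifest for a run
#'
#' Records the configuration hash, the seeds in play, the package version
#' and checksums of any weight/result files, plus a combined manifest hash
#' over exactly those fields. Two runs with the same configuration, seeds
#' and files produce the same hash; the hash is recomputable from the
#' stored fields.
#'
#' @param cfg a `run_config`.
#' @param seeds named list/vector of seeds used by the run.
#' @param files character vector of artifact paths to checksum.
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(cfg, seeds = list(), files = character()) {
  checksums <- if (length(files)) {
    vapply(files, function(f) unname(tools::md5sum(f)), character(1))
  } else {
    character(0)
  }
  core <- list(config_hash = .hash_obj(unclass(cfg)),
               seeds = seeds,
               package_version = as.character(utils::packageVersion("tomsnn")),
               file_checksums = as.list(checksums))
  structure(c(core, list(hash = .hash_obj(core))), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s (config %s, tomsnn %s, %d files)\n",
              x$hash, x$config_hash, x$package_version,
              length(x$file_checksums)))
  invisible(x)
}
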