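#' Save and load network weights
#'
#' Serialises a [decision_network()] or a [tom_networks()] bundle (weights,
#' eligibility traces and all hyperparameters) to a single JSON file at full
#' double precision, and restores it exactly.
#'
#' @param net a `decision_network` or `tom_networks` object.
#' @param path file path.
#' @export
save_network <- function(net, path) {
  jsonlite::write_json(.net_to_list(net), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  .list_to_net(jsonlite::read_json(path, simplifyVector = TRUE))
}

.syn_to_list <- function(syn) {
  list(weights = unclass(syn$weights), traces = unclass(syn$traces),
       tau_e = syn$tau_e, learning_rate = syn$learning_rate)
}

.list_to_syn <- function(x) {
  w <- as.matrix(x$weights)
  syn <- synapse_matrix(nrow(w), ncol(w), weights = w,
                        tau_e = x$tau_e, learning_rate = x$learning_rate)
  syn$traces <- as.matrix(x$traces)
  syn
}

.subnet_to_list <- function(net) {
  list(syn = .syn_to_list(net$syn),
       labels = net$partition$labels,
       neurons_per_population = net$partition$neurons_per_population,
       window = net$window, gain = net$gain, bias = net$bias,
       neuron = unclass(net$neuron), stdp = unclass(net$stdp),
       inhibition = net$inhibition$strength)
}

.list_to_subnet <- function(x, cls = NULL) {
  net <- list(
    syn = .list_to_syn(x$syn),
    partition = population_partition(x$labels, x$neurons_per_population),
    window = as.integer(x$window), gain = x$gain, bias = x$bias,
    neuron = do.call(neuron_params, as.list(x$neuron)),
    stdp = do.call(stdp_params, as.list(x$stdp)),
    inhibition = lateral_inhibition_config(x$inhibition)
  )
  if (!is.null(cls)) class(net) <- cls
  net
}

.net_to_list <- function(net) {
  if (inherits(net, "decision_network")) {
    c(list(type = "decision_network"), .subnet_to_list(net))
  } else if (inherits(net, "tom_networks")) {
    list(type = "tom_networks",
         policy = .subnet_to_list(net$policy),
         action = .subnet_to_list(net$action),
         safety = .subnet_to_list(net$safety))
  } else {
    .stopf("cannot serialize object of class '%s'", class(net)[1])
  }
}

.list_to_net <- function(x) {
  if (identical(x$type, "decision_network")) {
    .list_to_subnet(x, cls = "decision_network")
  } else if (identical(x$type, "tom_networks")) {
    structure(list(perspective = perspective_network(),
                   policy = .list_to_subnet(x$policy),
                   action = .list_to_subnet(x$action),
                   safety = .list_to_subnet(x$safety)),
              class = "tom_networks")
  } else {
    .stopf("unrecognized network file (type '%s')", x$type %||% "missing")
  }
}

#' Export a spike raster to CSV
#'
#' Long format, one row per spike: `neuron`, `timestep`.
#'
#' @param raster a binary spike raster (neurons x steps).
#' @param path output CSV path.
#' @export
write_spike_raster_csv <- function(raster, path) {
  idx <- which(raster == 1L, arr.ind = TRUE)
  df <- data.frame(neuron = idx[, 1], timestep = idx[, 2])
  df <- df[order(df$timestep, df$neuron), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write evaluation results to CSV
#'
#' @param results a [run_condition()] data frame.
#' @param path output CSV path.
#' @export
write_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
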