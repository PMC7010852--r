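# Structured run configuration: one flat list of stage parameters with
# the published defaults, overridable from a YAML file (and, in the CLI,
# by flags, which win over file values).

#' Default run configuration
#'
#' All stage parameters with their standard defaults: restart probability
#' 0.05; gene network embedding 600 dims within an 800-dim gene feature
#' vector; 200-dim disease features (100 network + 100 table); completion
#' rank `k = 200`, ridge `lambda = 0.02`, PU weight `alpha = 0.0035`;
#' evaluation cutoff `r = 100`; autoencoder noise factor 0.2, batch 150,
#' 100 epochs, Adam step 1e-3.
#'
#' @return Named list of parameters.
#' @export
default_run_config <- function() {
  list(
    restart_prob = 0.05,
    rwr_tol = 1e-6,
    rwr_max_iter = 1000L,
    gene_embed_dim = 600L,
    disease_embed_dim = 100L,
    gene_feature_dim = 800L,
    disease_feature_dim = 200L,
    dae_noise_factor = 0.2,
    dae_batch_size = 150L,
    dae_epochs = 100L,
    dae_learning_rate = 1e-3,
    k = 200L,
    lambda = 0.02,
    alpha = 0.0035,
    max_sweeps = 50L,
    objective_rel_tol = 1e-5,
    r = 100L,
    seed = 7L
  )
}

#' Read a run configuration from YAML
#'
#' Values in the file override the defaults of [default_run_config()];
#' unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of parameters.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  utils::modifyList(cfg, user)
}
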