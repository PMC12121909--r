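#' Default configuration of the simulated paradigm
#'
#' Bundles the default body, plan geometry, policy, internal model, feedback
#' gains, ecological weights and protocol counts into one list, which every
#' entry point accepts. Individual pieces can be replaced before a run.
#'
#' @return named list with elements `body` ([body_params()]), `policy`
#'   ([policy_distribution()]), `model` ([internal_model()]), `model_rho`
#'   (de-adaptation shift fraction), `gains` ([feedback_gains()]), `eco`
#'   (reward weights and bias decay) and `protocol` ([protocol_config()]).
#' @export
default_config <- function() {
  list(body = body_params(),
       policy = policy_distribution(),
       model = internal_model(),
       model_rho = 0.1,
       gains = feedback_gains(),
       eco = list(success_bonus = 1, safety_weight = 0.5,
                  effort_weight = 0.5, bias_decay_steps = 3),
       protocol = protocol_config())
}

#' Read a configuration from a YAML file
#'
#' Recognized top-level blocks: `body`, `policy`, `model`, `gains`, `eco`,
#' `protocol`; fields within a block override the defaults, e.g.
#' `body: {mass: 70, perturbation_gain_K: 3}`.
#'
#' @param path YAML file path.
#' @return configuration list as from [default_config()].
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(obj, upd, ctor) {
    if (is.null(upd)) return(obj)
    args <- utils::modifyList(unclass(obj)[names(formals(ctor))], upd)
    args <- args[!vapply(args, is.null, TRUE)]
    do.call(ctor, args)
  }
  cfg$body <- merge_into(cfg$body, y$body, body_params)
  cfg$policy <- merge_into(cfg$policy, y$policy, policy_distribution)
  cfg$gains <- merge_into(cfg$gains, y$gains, feedback_gains)
  cfg$protocol <- merge_into(cfg$protocol, y$protocol, protocol_config)
  if (!is.null(y$model)) {
    if (!is.null(y$model$learning_rate_eta)) {
      cfg$model$learning_rate_eta <- y$model$learning_rate_eta
    }
    if (!is.null(y$model$lambda)) cfg$model$lambda <- y$model$lambda
    if (!is.null(y$model$rho)) cfg$model_rho <- y$model$rho
  }
  if (!is.null(y$eco)) cfg$eco <- utils::modifyList(cfg$eco, y$eco)
  cfg
}
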