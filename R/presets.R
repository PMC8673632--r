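# Shipped configurations: the optimised per-specimen feature and
# hyperparameter sets for the four reference scans (one per classifier), and
# two small "synthetic" configurations sized for the bundled phantom
# generator and the test suite.

preset_table <- function() {
  rf <- function(h1r, h1k, h2s, h2r, h2k, ls, lr, trees)
    list(features = feature_config(histogram_spec(h1r, 0L, h1k),
                                   histogram_spec(h2r, h2s, h2k),
                                   lbp_spec(ls, lr)),
         classifier = rf_spec(trees))
  nn <- function(h1r, h1k, h2s, h2r, h2k, ls, lr, l1, l2, dr, sd, mb)
    list(features = feature_config(histogram_spec(h1r, 0L, h1k),
                                   histogram_spec(h2r, h2s, h2k),
                                   lbp_spec(ls, lr)),
         classifier = nn_spec(l1, l2, dr, sd, mb))
  list(
    `dog-rf`      = rf(3, 32, 0, 12, 16, 0, 15, 64),
    `raptor-rf`   = rf(6,  8, 0, 27, 32, 1, 27, 64),
    `ibis-rf`     = rf(5,  8, 0, 21, 32, 1, 20, 64),
    `ibis-jar-rf` = rf(7, 32, 2, 24, 16, 0, 30, 64),
    `dog-nn`      = nn(7, 16, 1,  6,  8, 1, 18, 256,  64, 0.40, 0.0001, 32),
    `raptor-nn`   = nn(8, 32, 2, 32, 32, 1, 28, 256,  64, 0.45, 0.0251, 32),
    `ibis-nn`     = nn(7,  8, 0, 27, 32, 1, 27,  64, 128, 0.25, 0.1585, 32),
    `ibis-jar-nn` = nn(7, 32, 2, 29, 16, 0, 28, 256,  64, 0.25, 0.0016, 32),
    `synthetic-rf` = rf(3, 8, 1, 6, 8, 0, 4, 32),
    `synthetic-nn` = nn(3, 8, 1, 6, 8, 0, 4, 64, 32, 0.1, 0.05, 32))
}

#' Names of the shipped configuration presets
#' @export
presets <- function() names(preset_table())

#' Retrieve a shipped configuration preset
#'
#' The specimen presets (`dog-rf` ... `ibis-jar-nn`) are the optimised
#' feature selections and model hyperparameters for the four reference
#' microtomography scans; the `synthetic-*` presets are small
#' configurations sized for the bundled phantom generator.
#'
#' @param name one of [presets()].
#' @return list with `features` (a [feature_config()]) and `classifier`
#'   (an [rf_spec()] or [nn_spec()]).
#' @export
preset_config <- function(name) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  tab[[name]]
}
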