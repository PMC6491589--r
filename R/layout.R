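#' Experiment layouts for multiplexed TMT designs
#'
#' A TMT layout maps every reporter channel of every technical replicate to
#' the biological condition it carries. Two layout flavours are supported:
#'
#' * **cofactor** (TMT6plex): each channel carries one clickable adenosine
#'   analogue (`2YnAd` or `6YnAd`) at a feeding concentration in mM.
#' * **inhibitor** (TMT10plex): each channel carries a PARP inhibitor
#'   (`Olaparib` or `Rucaparib`) at a treatment concentration in uM, or the
#'   vehicle control (`none`, 0 uM).
#'
#' Observations are ordered replicate-major: all channels of the first
#' replicate, then all channels of the second, and so on. Observation keys
#' are `"<replicate>.C<channel>"`.
#'
#' @param channels data.frame describing the channels of one plex, with a
#'   `channel` column (0-based reporter index) plus condition columns
#'   (`cofactor` + `conc_mM`, or `inhibitor` + `conc_uM`).
#' @param replicates character vector of replicate identifiers, in order.
#' @param type `"cofactor"` or `"inhibitor"`.
#' @return An object of class `tmt_layout`.
#' @export
tmt_layout <- function(channels, replicates, type = c("cofactor", "inhibitor")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(channels), length(replicates) >= 1L)
  if (anyDuplicated(replicates)) stop("replicate identifiers must be unique")
  if (!"channel" %in% names(channels)) stop("channels must have a 'channel' column")
  if (anyDuplicated(channels$channel)) stop("channel indices must be unique within a replicate")
  need <- if (type == "cofactor") c("cofactor", "conc_mM") else c("inhibitor", "conc_uM")
  miss <- setdiff(need, names(channels))
  if (length(miss)) stop("channels lacks column(s): ", paste(miss, collapse = ", "))
  conc <- channels[[need[2L]]]
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (type == "cofactor" && !all(channels$cofactor %in% c("2YnAd", "6YnAd")))
    stop("cofactor labels must be '2YnAd' or '6YnAd'")
  if (type == "inhibitor" && !all(channels$inhibitor %in% c("Olaparib", "Rucaparib", "none")))
    stop("inhibitor labels must be 'Olaparib', 'Rucaparib' or 'none'")
  if (type == "inhibitor" && any((channels$inhibitor == "none") != (conc == 0)))
    stop("'none' channels must have concentration 0 and vice versa")
  structure(
    list(replicates = as.character(replicates),
         channels = channels[order(channels$channel), , drop = FALSE],
         type = type),
    class = "tmt_layout")
}

#' @describeIn tmt_layout TMT6plex cofactor-preference layout: both analogues
#'   at each concentration of a dilution series (defaults: 1, 0.5, 0.25 mM),
#'   channels ordered 2YnAd high-to-low then 6YnAd high-to-low.
#' @param concentrations numeric vector of feeding concentrations (mM).
#' @export
cofactor_layout <- function(concentrations = c(1, 0.5, 0.25),
                            replicates = c("R1", "R2")) {
  stopifnot(all(concentrations > 0))
  k <- length(concentrations)
  channels <- data.frame(
    channel = seq_len(2L * k) - 1L,
    cofactor = rep(c("2YnAd", "6YnAd"), each = k),
    conc_mM = rep(concentrations, 2L),
    stringsAsFactors = FALSE)
  tmt_layout(channels, replicates, "cofactor")
}

#' @describeIn tmt_layout TMT10plex PARP-inhibitor layout: Olaparib at the
#'   dose series then its vehicle control, followed by Rucaparib likewise,
#'   so with defaults reporters 0, 4, 5 and 9 are the 25 uM / 0 uM channels.
#' @export
inhibitor_layout <- function(concentrations = c(25, 5, 1, 0.2, 0),
                             replicates = c("R1", "R2")) {
  stopifnot(all(concentrations >= 0), sum(concentrations == 0) == 1L)
  k <- length(concentrations)
  inh <- function(drug) ifelse(concentrations == 0, "none", drug)
  channels <- data.frame(
    channel = seq_len(2L * k) - 1L,
    inhibitor = c(inh("Olaparib"), inh("Rucaparib")),
    conc_uM = rep(concentrations, 2L),
    stringsAsFactors = FALSE)
  tmt_layout(channels, replicates, "inhibitor")
}

#' Observation table of a layout
#'
#' Expands a layout to one row per (replicate, channel) observation in
#' replicate-major order, with the observation key used as column name in
#' intensity matrices.
#'
#' @param layout a [tmt_layout].
#' @return data.frame with columns `key`, `replicate`, `channel` and the
#'   layout's condition columns.
#' @export
layout_observations <- function(layout) {
  stopifnot(inherits(layout, "tmt_layout"))
  obs <- do.call(rbind, lapply(layout$replicates, function(r) {
    cbind(data.frame(replicate = r, stringsAsFactors = FALSE), layout$channels)
  }))
  obs <- cbind(key = paste0(obs$replicate, ".C", obs$channel), obs)
  obs$key <- as.character(obs$key)
  rownames(obs) <- NULL
  obs
}

#' @export
print.tmt_layout <- function(x, ...) {
  cat(sprintf("TMT %s layout: %d replicate(s) x %d channels\n",
              x$type, length(x$replicates), nrow(x$channels)))
  print(x$channels, row.names = FALSE)
  invisible(x)
}
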