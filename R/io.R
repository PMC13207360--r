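# Session persistence: EEG as gzipped delimited text (channels in columns,
# labels in the header), events/communication/actions/outcomes as CSV, and
# session metadata (config echo, seed, schema version, config hash) as JSON.

SESSION_SCHEMA_VERSION <- "1.0"

#' Write a session bundle to a directory
#'
#' @param session a `tg_session`.
#' @param dir target directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "tg_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) data.table::fwrite(df, file.path(dir, name))
  if (!is.null(session$eeg)) {
    eeg <- data.table::as.data.table(t(session$eeg))
    data.table::setnames(eeg, session$channel_names)
    data.table::fwrite(eeg, file.path(dir, "eeg.csv.gz"))
  }
  w(as.data.frame(session$schedule), "events.csv")
  w(session$comm, "comm.csv")
  w(session$steps, "actions.csv")
  w(session$outcomes, "outcomes.csv")
  w(session$latent, "latent.csv")
  meta <- list(schema_version = SESSION_SCHEMA_VERSION,
               seed = session$config$seed,
               score = session$score,
               config = unclass(session$config),
               config_hash = config_hash(session$config))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a session bundle back from disk
#'
#' @param dir directory written by [write_session()].
#' @return a `tg_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  cfgl <- meta$config
  cfg <- session_config(duration_s = cfgl$duration_s,
                        sample_rate = cfgl$sample_rate,
                        n_channels = cfgl$n_channels,
                        condition = cfgl$condition,
                        warmup_s = cfgl$warmup_s,
                        event_rates = as.list(cfgl$event_rates),
                        secondary_duration_s = cfgl$secondary_duration_s,
                        behavior = as.list(cfgl$behavior),
                        latent = as.list(cfgl$latent),
                        eeg = as.list(cfgl$eeg),
                        seed = cfgl$seed)
  r <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) tg_stop("read_session: missing file ", p)
    as.data.frame(data.table::fread(p))
  }
  eeg <- NULL
  chn <- NULL
  ep <- file.path(dir, "eeg.csv.gz")
  if (file.exists(ep)) {
    et <- utils::read.csv(gzfile(ep), check.names = FALSE)
    chn <- colnames(et)
    eeg <- t(as.matrix(et))
    rownames(eeg) <- chn
  }
  sched <- r("events.csv")
  class(sched) <- c("tg_schedule", "data.frame")
  latent <- r("latent.csv")
  class(latent) <- c("tg_latent", "data.frame")
  comm <- r("comm.csv")
  if (!nrow(comm)) comm <- data.frame(time_s = numeric(0), gate = character(0))
  structure(list(eeg = eeg, sample_rate = cfg$sample_rate,
                 channel_names = chn %||% electrode_layout()$label,
                 schedule = sched, latent = latent, steps = r("actions.csv"),
                 comm = comm, outcomes = r("outcomes.csv"),
                 score = meta$score, config = cfg),
            class = "tg_session")
}
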