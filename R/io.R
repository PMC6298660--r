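# CSV I/O in the study's supplementary-file layout: a long edge list
# (ego_id, alter_id, wave) and a wide behavior table (id, T1..Tk).

find_col <- function(df, candidates, what, file) {
  hit <- match(tolower(candidates), tolower(names(df)))
  hit <- hit[!is.na(hit)]
  if (!length(hit))
    stop("cannot find a ", what, " column in ", file,
         " (looked for: ", paste(candidates, collapse = ", "), ")")
  names(df)[hit[1]]
}

#' Read a longitudinal panel from CSV files
#'
#' Expects a long-format edge list with columns identifying ego, alter and
#' wave, and a wide-format behavior table with an id column followed by one
#' column per wave.  Column names are matched case-insensitively against
#' common candidates (`ego_id`/`ego`/`from`, `alter_id`/`alter`/`to`,
#' `wave`/`time`/`t`; `id`/`ego_id`); unrecognized extra columns are ignored
#' with a warning.  The actor universe is the id set of the behavior table.
#'
#' @param links_file CSV edge list path.
#' @param bmi_file CSV wide behavior table path.
#' @param covariates_file optional CSV with columns id, male, race,
#'   first_year, floor.
#' @param bmi_type `"auto"` (default), `"kgm2"` or `"category"`.  Raw kg/m^2
#'   values are coded onto the 11-category scale via [code_bmi()]; `"auto"`
#'   treats the values as raw when any exceeds the category count or is
#'   fractional.
#' @return list with `panel` (a [wave_panel()]) and, when requested,
#'   `covariates` (a [covariate_table()]).
#' @details Duplicate (ego, alter, wave) rows are collapsed with a warning;
#'   self-nominations are dropped with a warning; an edge naming an actor id
#'   absent from the behavior table is an error.  Actors with missing
#'   behavior at a wave are flagged non-participating at that wave.
#' @export
read_panel <- function(links_file, bmi_file, covariates_file = NULL,
                       bmi_type = c("auto", "kgm2", "category")) {
  bmi_type <- match.arg(bmi_type)
  bmi <- read.csv(bmi_file, stringsAsFactors = FALSE, check.names = FALSE)
  idc <- find_col(bmi, c("id", "ego_id", "actor", "actor_id"), "id", bmi_file)
  wave_cols <- setdiff(names(bmi), idc)
  if (length(wave_cols) < 2) stop("behavior table must have at least two wave columns")
  ids <- as.character(bmi[[idc]])
  if (anyDuplicated(ids)) stop("duplicate actor ids in ", bmi_file)
  n <- length(ids)
  vals <- as.matrix(bmi[, wave_cols, drop = FALSE])
  storage.mode(vals) <- "double"

  if (bmi_type == "auto") {
    v <- vals[!is.na(vals)]
    bmi_type <- if (any(v > 11 | v != round(v))) "kgm2" else "category"
  }
  if (bmi_type == "kgm2") {
    codes <- apply(vals, 2, code_bmi)
    raw <- vals
  } else {
    codes <- vals
    storage.mode(codes) <- "integer"
    raw <- NULL
  }

  links <- read.csv(links_file, stringsAsFactors = FALSE, check.names = FALSE)
  egoc <- find_col(links, c("ego_id", "ego", "from", "source"), "ego", links_file)
  altc <- find_col(links, c("alter_id", "alter", "to", "target"), "alter", links_file)
  wavc <- find_col(links, c("wave", "time", "t", "period"), "wave", links_file)
  extra <- setdiff(names(links), c(egoc, altc, wavc))
  if (length(extra))
    warning("ignoring unrecognized column(s) in ", links_file, ": ",
            paste(extra, collapse = ", "))
  ego <- as.character(links[[egoc]])
  alt <- as.character(links[[altc]])
  wav <- links[[wavc]]
  wave_levels <- if (is.numeric(wav)) sort(unique(wav)) else unique(wav)
  widx <- match(wav, wave_levels)
  if (length(wave_levels) > length(wave_cols))
    stop("edge list has more waves than the behavior table")

  unknown <- setdiff(unique(c(ego, alt)), ids)
  if (length(unknown))
    stop("edge list names actor id(s) absent from the behavior table: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  self <- ego == alt
  if (any(self)) {
    warning("dropping ", sum(self), " self-nomination row(s)")
    ego <- ego[!self]; alt <- alt[!self]; widx <- widx[!self]
  }
  key <- paste(ego, alt, widx)
  if (anyDuplicated(key)) {
    warning("collapsing ", sum(duplicated(key)), " duplicated edge row(s)")
    keep <- !duplicated(key)
    ego <- ego[keep]; alt <- alt[keep]; widx <- widx[keep]
  }

  waves <- lapply(seq_along(wave_cols), function(m) {
    adj <- matrix(0L, n, n)
    sel <- widx == m
    if (any(sel))
      adj[cbind(match(ego[sel], ids), match(alt[sel], ids))] <- 1L
    list(adjacency = adj, behavior = codes[, m],
         bmi = if (is.null(raw)) NULL else raw[, m],
         participating = !is.na(codes[, m]))
  })
  panel <- wave_panel(waves, actor_ids = ids)

  covariates <- NULL
  if (!is.null(covariates_file)) {
    cv <- read.csv(covariates_file, stringsAsFactors = FALSE)
    cv <- cv[match(ids, as.character(cv$id)), ]
    if (any(is.na(cv$id))) stop("covariate table is missing some actor ids")
    covariates <- covariate_table(cv$id, cv$male, cv$race, cv$first_year,
                                  cv$floor)
  }
  list(panel = panel, covariates = covariates)
}

#' Write a panel to CSV files in the supplementary-file layout
#'
#' Inverse of [read_panel()]: a long edge list (ego_id, alter_id, wave) and a
#' wide behavior table (id, T1..Tk).  Behavior is written as raw BMI when the
#' panel carries raw values and `bmi_type = "kgm2"`, otherwise as category
#' codes.
#'
#' @param panel a `wave_panel`.
#' @param links_file,bmi_file output paths.
#' @param bmi_type `"category"` (default) or `"kgm2"`.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, links_file, bmi_file,
                        bmi_type = c("category", "kgm2")) {
  bmi_type <- match.arg(bmi_type)
  validate_wave_panel(panel)
  ids <- panel$actor_ids
  edges <- do.call(rbind, lapply(seq_along(panel$waves), function(m) {
    w <- which(panel$waves[[m]]$adjacency == 1L, arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    data.frame(ego_id = ids[w[, 1]], alter_id = ids[w[, 2]], wave = m)
  }))
  if (is.null(edges))
    edges <- data.frame(ego_id = character(), alter_id = character(),
                        wave = integer())
  write.csv(edges, links_file, row.names = FALSE)

  beh <- sapply(panel$waves, function(w) {
    if (bmi_type == "kgm2") {
      if (is.null(w$bmi)) stop("panel carries no raw BMI values")
      w$bmi
    } else w$behavior
  })
  beh <- as.data.frame(beh)
  names(beh) <- paste0("T", seq_along(panel$waves))
  write.csv(cbind(id = ids, beh), bmi_file, row.names = FALSE)
  invisible(c(links_file, bmi_file))
}

#' Write a covariate table to CSV
#'
#' @param covariates a `covariate_table`.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_covariates <- function(covariates, file) {
  write.csv(as.data.frame(covariates), file, row.names = FALSE)
  invisible(file)
}
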