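# Reading, validating and writing the standard file layouts.

cohort_columns <- function() {
  c("swimmer_id", "session", "sex", "age_y", "height_cm",
    "sitting_height_cm", "arm_span_cm", "body_mass_kg",
    "breast_t25_s", "breast_t10_s", "breast_t3cycles_s",
    "fly_t25_s", "fly_t10_s", "fly_t3cycles_s")
}

#' Read a cohort table
#'
#' Reads the standard longitudinal input CSV: one row per swimmer per
#' session with columns `swimmer_id`, `session` (`before`/`after`), `sex`
#' (`F`/`M`), `age_y`, `height_cm`, `sitting_height_cm`, `arm_span_cm`,
#' `body_mass_kg` and, per technique `x` in `breast`, `fly`: `x_t25_s`,
#' `x_t10_s`, `x_t3cycles_s`. UTF-8, decimal point, header required.
#'
#' @param path Path to a CSV file.
#' @return Data frame with the columns above.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    swim_stop(sprintf("input file not found: %s", path), "swimnet_io_error")
  }
  x <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(cohort_columns(), names(x))
  if (length(missing)) {
    swim_stop(sprintf("input is missing required column(s): %s",
                      paste(missing, collapse = ", ")),
              "swimnet_schema_error")
  }
  x[, cohort_columns()]
}

# One violation record.
violation <- function(row, rule, message) {
  data.frame(row = row, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a cohort table
#'
#' Checks the input schema and measurement invariants without aborting:
#' required columns, recognized `session` and `sex` codes, no duplicated
#' (swimmer, session) rows, both sessions present per swimmer, positive
#' measurements, sitting height below stature, and `t10 < t25` for each
#' technique. Row numbers refer to the table as read (header excluded).
#'
#' @param x Cohort data frame or path to a CSV file.
#' @return Data frame of violations (`row`, `rule`, `message`); zero rows
#'   when the input is valid.
#' @export
validate_cohort <- function(x) {
  if (is.character(x)) x <- read_cohort(x)
  out <- violation(integer(), character(), character())
  missing <- setdiff(cohort_columns(), names(x))
  if (length(missing)) {
    return(violation(NA_integer_, "schema",
                     sprintf("missing column(s): %s",
                             paste(missing, collapse = ", "))))
  }
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (!r$session %in% c("before", "after")) {
      out <- rbind(out, violation(i, "session",
                                  sprintf("unknown session '%s'", r$session)))
    }
    if (!toupper(r$sex) %in% c("F", "M", "GIRL", "BOY", "FEMALE", "MALE")) {
      out <- rbind(out, violation(i, "sex",
                                  sprintf("unknown sex '%s'", r$sex)))
    }
    num <- unlist(r[setdiff(cohort_columns(), c("swimmer_id", "session",
                                                "sex"))])
    if (any(is.na(num)) || any(num <= 0)) {
      out <- rbind(out, violation(i, "positivity",
                                  "non-positive or missing measurement"))
    } else {
      if (r$sitting_height_cm >= r$height_cm) {
        out <- rbind(out, violation(i, "sitting_height",
                                    "sitting height not below stature"))
      }
      for (tech in c("breast", "fly")) {
        if (r[[paste0(tech, "_t10_s")]] >= r[[paste0(tech, "_t25_s")]]) {
          out <- rbind(out, violation(
            i, "split_times",
            sprintf("%s 10-m split not below 25-m time", tech)))
        }
      }
    }
  }
  dup <- duplicated(x[, c("swimmer_id", "session")])
  for (i in which(dup)) {
    out <- rbind(out, violation(i, "duplicate",
                                sprintf("duplicated session '%s' for '%s'",
                                        x$session[i], x$swimmer_id[i])))
  }
  tab <- table(x$swimmer_id, factor(x$session,
                                    levels = c("before", "after")))
  unpaired <- rownames(tab)[rowSums(tab >= 1) < 2]
  for (id in unpaired) {
    out <- rbind(out, violation(NA_integer_, "pairing",
                                sprintf("swimmer '%s' lacks both sessions",
                                        id)))
  }
  rownames(out) <- NULL
  out
}

round_df <- function(x, digits) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], round, digits = digits)
  x
}

#' Write the network weight matrix
#'
#' Writes the partial-correlation matrix the way seasonal-change studies
#' print it -- lower triangle, fixed precision -- plus a full-precision
#' companion and an edge list with the sign convention used for network
#' coloring (positive = green, negative = red).
#'
#' @param fit A [pcnetwork()] fit.
#' @param path Output CSV path for the rounded lower-triangle matrix; the
#'   companion files get `_full` and `_edges` suffixes.
#' @param digits Rounding for the display matrix, default 2.
#' @param graphml Optional path for a GraphML export (with `group` node
#'   attribute); skipped when `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_weight_matrix <- function(fit, path, digits = 2, graphml = NULL) {
  w <- fit$weights
  disp <- round(w, digits)
  disp[upper.tri(disp, diag = TRUE)] <- NA
  disp_df <- data.frame(node = rownames(w), disp, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write.csv(disp_df, path, row.names = FALSE, na = "")
  full_path <- sub("(\\.csv)?$", "_full.csv", path)
  write.csv(data.frame(node = rownames(w), w, check.names = FALSE),
            full_path, row.names = FALSE)
  ut <- which(upper.tri(w) & abs(w) > fit$threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_a = rownames(w)[ut[, 1]],
    node_b = colnames(w)[ut[, 2]],
    weight = w[ut],
    sign = ifelse(w[ut] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  edges_path <- sub("(\\.csv)?$", "_edges.csv", path)
  write.csv(edges, edges_path, row.names = FALSE)
  paths <- c(path, full_path, edges_path)
  if (!is.null(graphml)) {
    g <- weight_graph(w, fit$threshold)
    igraph::V(g)$group <- fit$nodes$group
    igraph::write_graph(g, graphml, format = "graphml")
    paths <- c(paths, graphml)
  }
  invisible(paths)
}

#' Write a centrality table
#'
#' Writes the z-scored centrality table (rounded, in the layout of the
#' published centrality tables) plus a full-precision raw-values
#' companion.
#'
#' @param ct A [centrality_table()] data frame.
#' @param path Output CSV path; the raw companion gets a `_raw` suffix.
#' @param digits Rounding for the z-score table, default 2.
#' @return Invisibly, the paths written.
#' @export
write_centrality <- function(ct, path, digits = 2) {
  disp <- ct[, c("node", "group", "excluded", "betweenness_z",
                 "closeness_z", "strength_z")]
  write.csv(round_df(disp, digits), path, row.names = FALSE)
  raw_path <- sub("(\\.csv)?$", "_raw.csv", path)
  write.csv(ct, raw_path, row.names = FALSE)
  invisible(c(path, raw_path))
}

#' Write an effect-size table
#'
#' Writes the seasonal effect-size summary as CSV (full precision) and as
#' a JSON array with one object per variable row.
#'
#' @param et An [effect_table()] data frame.
#' @param path Output CSV path; the JSON companion swaps the extension.
#' @return Invisibly, the paths written.
#' @export
write_effect_table <- function(et, path) {
  write.csv(et, path, row.names = FALSE)
  json_path <- sub("(\\.csv)?$", ".json", path)
  jsonlite::write_json(et, json_path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(path, json_path))
}
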