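# Preset model ensembles in three groups:
#   efficient  -- repeat models only (fast, modest ratios)
#   optimized  -- FCMs + RMs (+ STCM), balanced
#   maximal    -- large ensembles, high orders, inverted-repeat updates
#
# Nine presets ship (levels 1..9, three per group). Every resolved parameter
# is serialized into the container, so presets can evolve without breaking
# decompression of existing archives.

profile_table <- function() {
  list(
    list(level = 1L, name = "efficient-1", group = "efficient",
         fcm = NULL, stcm = NULL,
         rm = list(k = 13, c = 8, beta = 0.9, limit = 7, n_models = 1)),
    list(level = 2L, name = "efficient-2", group = "efficient",
         fcm = NULL, stcm = NULL,
         rm = list(k = 13, c = 8, beta = 0.9, limit = 7, n_models = 3)),
    list(level = 3L, name = "efficient-3", group = "efficient",
         fcm = NULL, stcm = NULL,
         rm = list(k = 14, c = 8, beta = 0.9, limit = 7, n_models = 4)),
    list(level = 4L, name = "optimized-1", group = "optimized",
         fcm = data.frame(k = c(1, 6, 11)), stcm = NULL,
         rm = list(k = 12, c = 8, beta = 0.9, limit = 7, n_models = 1)),
    list(level = 5L, name = "optimized-2", group = "optimized",
         fcm = data.frame(k = c(3, 8, 13)),
         stcm = data.frame(k = 13, t = 3, share = 3),
         rm = list(k = 13, c = 8, beta = 0.9, limit = 7, n_models = 2)),
    list(level = 6L, name = "optimized-3", group = "optimized",
         fcm = data.frame(k = c(2, 5, 9, 13)),
         stcm = data.frame(k = 13, t = 3, share = 4),
         rm = list(k = 13, c = 8, beta = 0.9, limit = 7, n_models = 2)),
    list(level = 7L, name = "maximal-1", group = "maximal",
         fcm = data.frame(k = c(1, 4, 8, 12, 14),
                          ir = c(FALSE, FALSE, FALSE, TRUE, TRUE)),
         stcm = data.frame(k = 14, t = 3, share = 5),
         rm = list(k = 13, c = 8, beta = 0.9, limit = 7, n_models = 3)),
    list(level = 8L, name = "maximal-2", group = "maximal",
         fcm = data.frame(k = c(1, 3, 6, 9, 12, 14),
                          ir = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)),
         stcm = data.frame(k = 14, t = 3, share = 6),
         rm = list(k = 13, c = 8, beta = 0.9, limit = 7, n_models = 4)),
    list(level = 9L, name = "maximal-3", group = "maximal",
         fcm = data.frame(k = c(1, 3, 5, 8, 11, 13, 14),
                          ir = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)),
         stcm = data.frame(k = c(13, 14), t = c(3, 3), share = c(6, 7)),
         rm = list(k = 14, c = 8, beta = 0.9, limit = 7, n_models = 4))
  )
}

#' Resolve a preset profile
#'
#' Maps a level (1..9) or preset name to a fully specified model ensemble.
#' Levels 1-3 are the *efficient* group (repeat models only), 4-6 *optimized*
#' (FCMs + RMs + STCM), 7-9 *maximal* (largest ensembles, inverted-repeat
#' updates on the high orders).
#'
#' @param selector Integer level 1..9, a preset name such as
#'   `"optimized-2"`, or an existing `copymix_profile` (returned unchanged).
#' @param seed Seed for the repeat-model candidate-selection LCG; stored in
#'   the container so the decoder replays identical selections.
#' @return A list of class `copymix_profile` with fields `name`, `group`,
#'   `level` and `config` (an [engine_config()]).
#' @examples
#' resolve_profile(1)$name
#' resolve_profile("maximal-3")$group
#' @export
resolve_profile <- function(selector = 5, seed = 1) {
  if (inherits(selector, "copymix_profile")) return(selector)
  tab <- profile_table()
  names_avail <- vapply(tab, `[[`, "", "name")
  entry <- if (is.numeric(selector)) {
    if (!selector %in% 1:9)
      stop("unknown preset level ", selector, "; available levels: 1..9 (",
           paste(names_avail, collapse = ", "), ")")
    tab[[as.integer(selector)]]
  } else {
    hit <- match(as.character(selector), names_avail)
    if (is.na(hit))
      stop("unknown preset '", selector, "'; available: ",
           paste(names_avail, collapse = ", "))
    tab[[hit]]
  }
  rm_cfg <- do.call(rm_config, c(entry$rm, list(lcg_seed = seed)))
  cfg <- engine_config(fcm = entry$fcm, stcm = entry$stcm, rm = rm_cfg)
  structure(list(name = entry$name, group = entry$group,
                 level = entry$level, config = cfg),
            class = "copymix_profile")
}

#' List available presets
#'
#' @return Data frame with one row per preset: level, name, group, model
#'   counts and the repeat-model anchor order.
#' @export
profile_list <- function() {
  tab <- profile_table()
  do.call(rbind, lapply(tab, function(e) data.frame(
    level = e$level, name = e$name, group = e$group,
    n_fcm = if (is.null(e$fcm)) 0L else nrow(e$fcm),
    n_stcm = if (is.null(e$stcm)) 0L else nrow(e$stcm),
    n_rm = e$rm$n_models, rm_k = e$rm$k,
    stringsAsFactors = FALSE)))
}

#' A-priori memory ceiling of a profile
#'
#' Upper bound, in entries, of the profile's table allocations: `4^k * c` for
#' the repeat-model cache-table plus the context-table slots of each FCM/STCM
#' (capped at `2^max_table_bits` contexts of 4 counters).
#'
#' @param profile A `copymix_profile`.
#' @return Named numeric vector with `cache_entries`, `context_slots` and
#'   `total`.
#' @export
profile_memory_bound <- function(profile) {
  cfg <- profile$config
  cache <- if (is.null(cfg$rm)) 0 else 4^cfg$rm$k * cfg$rm$c
  slots <- 0
  count_tab <- function(k) 4 * min(4^k, 2^cfg$max_table_bits)
  if (!is.null(cfg$fcm)) slots <- slots + sum(vapply(cfg$fcm$k, count_tab, 0))
  if (!is.null(cfg$stcm))
    slots <- slots + sum(vapply(seq_len(nrow(cfg$stcm)), function(i)
      if (cfg$stcm$share[i] > 0) 0 else count_tab(cfg$stcm$k[i]), 0))
  c(cache_entries = cache, context_slots = slots, total = cache + slots)
}

#' @export
print.copymix_profile <- function(x, ...) {
  cfg <- x$config
  cat("<copymix_profile> ", x$name, " (group: ", x$group,
      ", level ", x$level, ")\n", sep = "")
  if (!is.null(cfg$fcm))
    cat("  FCMs: k =", paste(cfg$fcm$k, collapse = ","),
        if (any(cfg$fcm$ir)) " (inverted repeats on high orders)" else "", "\n")
  if (!is.null(cfg$stcm))
    cat("  STCMs: k =", paste(cfg$stcm$k, collapse = ","),
        " t =", paste(cfg$stcm$t, collapse = ","), "\n")
  if (!is.null(cfg$rm))
    cat("  RMs: ", cfg$rm$n_models, " slot(s), k=", cfg$rm$k, " c=", cfg$rm$c,
        " beta=", cfg$rm$beta, " L=", cfg$rm$limit, "\n", sep = "")
  invisible(x)
}

# serialize a profile (resolved parameters) to JSON for the container
profile_to_json <- function(profile) {
  cfg <- profile$config
  jsonlite::toJSON(list(
    name = profile$name, group = profile$group, level = profile$level,
    fcm = cfg$fcm, stcm = cfg$stcm, rm = cfg$rm, gammas = cfg$gammas,
    weight_floor = cfg$weight_floor, prob_floor = cfg$prob_floor,
    max_table_bits = cfg$max_table_bits
  ), auto_unbox = TRUE, digits = NA, null = "null")
}

profile_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  rm_cfg <- if (is.null(p$rm)) NULL else do.call(rm_config, as.list(p$rm))
  cfg <- engine_config(fcm = p$fcm, stcm = p$stcm, rm = rm_cfg,
                       gammas = p$gammas, weight_floor = p$weight_floor,
                       prob_floor = p$prob_floor,
                       max_table_bits = p$max_table_bits)
  structure(list(name = p$name, group = p$group, level = p$level,
                 config = cfg),
            class = "copymix_profile")
}
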