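#' Build a sterilisation-department instance
#'
#' An instance bundles everything the simulator and the sizing heuristics
#' need to know about one hospital: the tray catalogue, the surgery mix
#' with weekday arrival rates and tray configurations, the workstation /
#' machine / staffing resources of the Central Sterilisation Services
#' (CSS) department, and the batch logistics for outpatient trays.
#'
#' All times of day are minutes from midnight; all durations are minutes.
#' Lognormal parameters (`*_mu`, `*_sigma`) are on the log scale — use
#' [lognormal_params()] to convert a natural-scale mean/sd.
#'
#' @param tray_types Tibble with columns `id`, `size_class` (S/M/L/XL),
#'   `compat_class` (trays of different classes are never washed in the
#'   same disinfector charge), `current_inventory`, `source`
#'   ("surgical" or "outpatient").
#' @param surgery_types Tibble with `id`, `duration_mu`, `duration_sigma`
#'   (log-scale lognormal parameters of the surgery duration, minutes).
#' @param surgery_rates Tibble with `surgery_type`, `weekday`
#'   (see [weekdays_short()]) and `rate` (expected surgeries per day).
#' @param configurations Tibble with `surgery_type`, `config_id`,
#'   `probability`; probabilities sum to 1 within a surgery type.
#' @param config_trays Tibble with `surgery_type`, `config_id`,
#'   `tray_type`, `n` — the multiset of trays a configuration requires.
#' @param workstations Tibble with `kind` ("pre_clean", "assemble",
#'   "wrap"), `count`, `capacity` (trays per station), `service_mu`,
#'   `service_sigma`.
#' @param machines Tibble with `kind` ("disinfector", "autoclave"),
#'   `count`, `capacity` (disinfector: size units; autoclave: trays),
#'   `layers`, `layer_units` (disinfector loading rack; `layers *
#'   layer_units == capacity`), `charge_minutes` (deterministic cycle),
#'   `load_mu`, `load_sigma`, `unload_mu`, `unload_sigma` (autoclaves have
#'   no unload stage; use NA), `start_threshold` (a free machine is only
#'   started once it can be filled to at least this fraction).
#' @param staff_shifts Tibble with `team` ("pre_cleaning",
#'   "post_cleaning"), `weekday`, `start`, `end` (minutes), `headcount`.
#' @param operating_rooms Character vector of OR identifiers.
#' @param batch_schedule List with `insertion_times` (strictly increasing
#'   times of day) and `batched_sources` (tray `source` labels whose used
#'   trays are returned to the CSS in batches, e.g. "outpatient").
#' @param outpatient_rate Expected outpatient procedures per day for each
#'   outpatient tray type.
#' @param outpatient_window Length-2 numeric, daily window in which
#'   outpatient demand occurs.
#' @param or_day_window Length-2 numeric, (open, close) of the OR day.
#' @param size_map Named integer vector mapping size classes to machine
#'   size units (default S=1, M=2, L=3, XL=4).
#'
#' @return An object of class `css_instance`.
#' @seealso [load_instance()], [validate_instance()], [toy_instance()]
#' @export
css_instance <- function(tray_types, surgery_types, surgery_rates,
                         configurations, config_trays, workstations,
                         machines, staff_shifts, operating_rooms,
                         batch_schedule = list(insertion_times = c(660, 960),
                                               batched_sources = "outpatient"),
                         outpatient_rate = 0,
                         outpatient_window = c(480, 1020),
                         or_day_window = c(480, 960),
                         size_map = c(S = 1L, M = 2L, L = 3L, XL = 4L)) {
  tray_types <- as_tibble(tray_types)
  tray_types$size_units <- as.integer(unname(size_map[tray_types$size_class]))
  inst <- structure(
    list(
      tray_types = tray_types,
      surgery_types = as_tibble(surgery_types),
      surgery_rates = as_tibble(surgery_rates),
      configurations = as_tibble(configurations),
      config_trays = as_tibble(config_trays),
      workstations = as_tibble(workstations),
      machines = as_tibble(machines),
      staff_shifts = as_tibble(staff_shifts),
      operating_rooms = as.character(operating_rooms),
      batch_schedule = list(
        insertion_times = parse_clock(batch_schedule$insertion_times),
        batched_sources = as.character(batch_schedule$batched_sources)
      ),
      outpatient_rate = as.numeric(outpatient_rate),
      outpatient_window = parse_clock(outpatient_window),
      or_day_window = parse_clock(or_day_window),
      size_map = size_map
    ),
    class = "css_instance"
  )
  inst
}

#' @export
print.css_instance <- function(x, ...) {
  cat("<css_instance>\n")
  cat("  tray types:     ", nrow(x$tray_types),
      " (", sum(x$tray_types$current_inventory), " trays in current stock)\n",
      sep = "")
  cat("  surgery types:  ", nrow(x$surgery_types), "\n", sep = "")
  cat("  operating rooms:", length(x$operating_rooms), "\n")
  cat("  machines:       ",
      paste(sprintf("%s x%d", x$machines$kind, x$machines$count),
            collapse = ", "), "\n")
  invisible(x)
}

#' Current-inventory policy of an instance
#'
#' Convenience accessor turning the `current_inventory` column of the tray
#' catalogue into an inventory policy tibble, comparable with the output
#' of the sizing heuristics.
#'
#' @param instance A `css_instance`.
#' @return Tibble with `tray_type` and `Q`.
#' @export
current_policy <- function(instance) {
  tibble(tray_type = instance$tray_types$id,
         Q = as.integer(instance$tray_types$current_inventory))
}

# ---------------------------------------------------------------------------
# Validation

push_violation <- function(msgs, cond, msg) {
  if (any(cond, na.rm = TRUE) || anyNA(cond)) c(msgs, msg) else msgs
}

#' Validate an instance
#'
#' Checks every structural invariant the simulator relies on. Violations
#' are returned as data, not raised: an empty character vector means the
#' instance is valid.
#'
#' @param instance A `css_instance`.
#' @return Character vector of violation messages (empty if valid).
#' @examples
#' validate_instance(toy_instance())
#' @export
validate_instance <- function(instance) {
  v <- character()
  tt <- instance$tray_types
  if (anyDuplicated(tt$id)) {
    v <- c(v, sprintf("tray type id '%s' is duplicated",
                      tt$id[duplicated(tt$id)][1]))
  }
  bad <- !tt$size_class %in% names(instance$size_map)
  if (any(bad)) {
    v <- c(v, sprintf("tray type '%s': unknown size class '%s'",
                      tt$id[bad], tt$size_class[bad]))
  }
  ok_units <- !is.na(tt$size_units) & tt$size_units >= 1
  if (!all(ok_units)) {
    v <- c(v, sprintf("tray type '%s': size_units must be >= 1", tt$id[!ok_units]))
  }
  bad <- is.na(tt$current_inventory) | tt$current_inventory < 0
  if (any(bad)) {
    v <- c(v, sprintf("tray type '%s': current_inventory must be >= 0", tt$id[bad]))
  }

  st <- instance$surgery_types
  bad <- is.na(st$duration_sigma) | st$duration_sigma < 0
  if (any(bad)) {
    v <- c(v, sprintf("surgery type '%s': duration_sigma must be >= 0", st$id[bad]))
  }
  sr <- instance$surgery_rates
  bad <- !sr$weekday %in% weekdays_short()
  if (any(bad)) {
    v <- c(v, sprintf("surgery type '%s': unknown weekday '%s'",
                      sr$surgery_type[bad], sr$weekday[bad]))
  }
  bad <- is.na(sr$rate) | sr$rate < 0
  if (any(bad)) {
    v <- c(v, sprintf("surgery type '%s': negative or missing rate on %s",
                      sr$surgery_type[bad], sr$weekday[bad]))
  }

  cfg <- instance$configurations
  ct <- instance$config_trays
  missing_cfg <- setdiff(st$id, cfg$surgery_type)
  if (length(missing_cfg)) {
    v <- c(v, sprintf("surgery type '%s': has no configurations", missing_cfg))
  }
  bad <- is.na(cfg$probability) | cfg$probability < 0 | cfg$probability > 1
  if (any(bad)) {
    v <- c(v, sprintf("surgery type '%s' config %d: probability outside [0, 1]",
                      cfg$surgery_type[bad], cfg$config_id[bad]))
  }
  sums <- tapply(cfg$probability, cfg$surgery_type, sum)
  off <- names(sums)[is.na(sums) | abs(sums - 1) > 1e-9]
  if (length(off)) {
    v <- c(v, sprintf("surgery type '%s': configuration probabilities sum != 1", off))
  }
  key_cfg <- paste(cfg$surgery_type, cfg$config_id)
  key_ct <- unique(paste(ct$surgery_type, ct$config_id))
  empty <- setdiff(key_cfg, key_ct)
  if (length(empty)) {
    v <- c(v, sprintf("configuration '%s' lists no trays", empty))
  }
  bad <- !ct$tray_type %in% tt$id
  if (any(bad)) {
    v <- c(v, sprintf("surgery type '%s' config %d: unknown tray id '%s'",
                      ct$surgery_type[bad], ct$config_id[bad], ct$tray_type[bad]))
  }
  bad <- is.na(ct$n) | ct$n < 1
  if (any(bad)) {
    v <- c(v, sprintf("surgery type '%s' config %d: tray count must be >= 1",
                      ct$surgery_type[bad], ct$config_id[bad]))
  }

  ws <- instance$workstations
  bad <- !ws$kind %in% c("pre_clean", "assemble", "wrap")
  if (any(bad)) v <- c(v, sprintf("workstation: unknown kind '%s'", ws$kind[bad]))
  bad <- is.na(ws$count) | ws$count < 1
  if (any(bad)) v <- c(v, sprintf("workstation '%s': count must be >= 1", ws$kind[bad]))
  bad <- is.na(ws$capacity) | ws$capacity < 1
  if (any(bad)) v <- c(v, sprintf("workstation '%s': capacity must be >= 1", ws$kind[bad]))
  bad <- !is.finite(ws$service_mu) | !is.finite(ws$service_sigma) | ws$service_sigma < 0
  if (any(bad)) {
    v <- c(v, sprintf("workstation '%s': non-finite or negative lognormal parameters",
                      ws$kind[bad]))
  }

  mc <- instance$machines
  bad <- !mc$kind %in% c("disinfector", "autoclave")
  if (any(bad)) v <- c(v, sprintf("machine: unknown kind '%s'", mc$kind[bad]))
  bad <- is.na(mc$count) | mc$count < 1
  if (any(bad)) v <- c(v, sprintf("machine '%s': count must be >= 1", mc$kind[bad]))
  bad <- is.na(mc$capacity) | mc$capacity < 1
  if (any(bad)) v <- c(v, sprintf("machine '%s': capacity must be >= 1", mc$kind[bad]))
  dis <- mc[mc$kind == "disinfector", ]
  if (nrow(dis)) {
    bad <- is.na(dis$layers) | is.na(dis$layer_units) |
      dis$layers * dis$layer_units != dis$capacity
    if (any(bad)) {
      v <- c(v, "disinfector: layers * layer_units must equal capacity")
    }
  }
  bad <- is.na(mc$start_threshold) | mc$start_threshold <= 0 | mc$start_threshold > 1
  if (any(bad)) {
    v <- c(v, sprintf("machine '%s': start_threshold must be in (0, 1]", mc$kind[bad]))
  }
  bad <- is.na(mc$charge_minutes) | mc$charge_minutes <= 0
  if (any(bad)) v <- c(v, sprintf("machine '%s': charge_minutes must be > 0", mc$kind[bad]))

  sh <- instance$staff_shifts
  bad <- !sh$team %in% c("pre_cleaning", "post_cleaning")
  if (any(bad)) v <- c(v, sprintf("staff shift: unknown team '%s'", sh$team[bad]))
  bad <- !sh$weekday %in% weekdays_short()
  if (any(bad)) v <- c(v, sprintf("staff shift: unknown weekday '%s'", sh$weekday[bad]))
  bad <- is.na(sh$start) | is.na(sh$end) | sh$start >= sh$end
  if (any(bad)) {
    v <- c(v, sprintf("staff shift (%s, %s): end must be after start",
                      sh$team[bad], sh$weekday[bad]))
  }
  bad <- is.na(sh$headcount) | sh$headcount < 1
  if (any(bad)) {
    v <- c(v, sprintf("staff shift (%s, %s): headcount must be >= 1",
                      sh$team[bad], sh$weekday[bad]))
  }

  bt <- instance$batch_schedule$insertion_times
  if (length(bt) && (anyNA(bt) || any(diff(bt) <= 0) || any(bt < 0) || any(bt >= 1440))) {
    v <- c(v, "batch insertion times must be strictly increasing times of day")
  }

  if (length(instance$operating_rooms) < 1) {
    v <- c(v, "instance must have at least one operating room")
  }
  w <- instance$or_day_window
  if (length(w) != 2 || anyNA(w) || w[1] >= w[2]) {
    v <- c(v, "or_day_window open must be before close")
  }
  if (is.na(instance$outpatient_rate) || instance$outpatient_rate < 0) {
    v <- c(v, "outpatient_rate must be >= 0")
  }
  v
}

assert_valid_instance <- function(instance) {
  v <- validate_instance(instance)
  if (length(v)) {
    stop("invalid instance:\n", paste("  -", v, collapse = "\n"), call. = FALSE)
  }
  invisible(instance)
}

# ---------------------------------------------------------------------------
# YAML round trip

check_keys <- function(x, required, optional, path) {
  if (!is.list(x)) stop("schema error at ", path, ": expected a mapping", call. = FALSE)
  nms <- names(x)
  missing <- setdiff(required, nms)
  if (length(missing)) {
    stop("schema error at ", path, ": missing required field '", missing[1], "'",
         call. = FALSE)
  }
  unknown <- setdiff(nms, c(required, optional))
  if (length(unknown)) {
    stop("schema error at ", path, ": unknown field '", unknown[1], "'",
         call. = FALSE)
  }
  invisible(x)
}

num_field <- function(x, key, path) {
  val <- x[[key]]
  if (!is.numeric(val) || length(val) != 1L || is.na(val)) {
    stop("schema error at ", path, "/", key, ": expected a number", call. = FALSE)
  }
  val
}

#' Read an instance from a YAML document
#'
#' The schema mirrors [css_instance()]; see the file produced by
#' [save_instance()] or `system.file("extdata", "toy_instance.yaml",
#' package = "traycycle")` for a worked example. Unknown keys are rejected
#' so that typos fail fast; lognormal parameters are log-scale
#' (see [lognormal_params()]). Optional resource sections default to the
#' mid-size-hospital reference parameters of [default_resources()].
#'
#' @param path Path to a YAML file (or a YAML string).
#' @return A validated `css_instance`.
#' @export
load_instance <- function(path) {
  doc <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  check_keys(doc,
             required = c("tray_types", "surgery_types", "operating_rooms"),
             optional = c("size_map", "workstations", "machines", "staff",
                          "batch_schedule", "outpatient_rate",
                          "outpatient_window", "or_day_window"),
             path = "<root>")

  size_map <- c(S = 1L, M = 2L, L = 3L, XL = 4L)
  if (!is.null(doc$size_map)) {
    size_map <- vapply(doc$size_map, as.integer, integer(1))
  }

  tray_types <- purrr::imap_dfr(doc$tray_types, function(t, i) {
    p <- paste0("tray_types[", i, "]")
    check_keys(t, required = c("id", "size_class"),
               optional = c("compat_class", "current_inventory", "source"), path = p)
    tibble(id = as.character(t$id),
           size_class = as.character(t$size_class),
           compat_class = as.character(t$compat_class %||% "regular"),
           current_inventory = as.integer(t$current_inventory %||% 0L),
           source = as.character(t$source %||% "surgical"))
  })

  st <- list(); sr <- list(); cfg <- list(); ct <- list()
  for (i in seq_along(doc$surgery_types)) {
    o <- doc$surgery_types[[i]]
    p <- paste0("surgery_types[", i, "]")
    check_keys(o, required = c("id", "duration_mu", "duration_sigma",
                               "rates", "configurations"),
               optional = character(), path = p)
    st[[i]] <- tibble(id = as.character(o$id),
                      duration_mu = num_field(o, "duration_mu", p),
                      duration_sigma = num_field(o, "duration_sigma", p))
    rates <- o$rates
    bad <- setdiff(names(rates), weekdays_short())
    if (length(bad)) {
      stop("schema error at ", p, "/rates: unknown weekday '", bad[1], "'",
           call. = FALSE)
    }
    full <- setNames(rep(0, 7), weekdays_short())
    for (d in names(rates)) full[[d]] <- num_field(rates, d, paste0(p, "/rates"))
    sr[[i]] <- tibble(surgery_type = o$id, weekday = names(full),
                      rate = unname(full))
    for (j in seq_along(o$configurations)) {
      cj <- o$configurations[[j]]
      pj <- paste0(p, "/configurations[", j, "]")
      check_keys(cj, required = c("probability", "trays"),
                 optional = character(), path = pj)
      cfg[[length(cfg) + 1L]] <- tibble(surgery_type = o$id, config_id = j,
                                        probability = num_field(cj, "probability", pj))
      if (!length(cj$trays)) stop("schema error at ", pj, "/trays: empty", call. = FALSE)
      ct[[length(ct) + 1L]] <- tibble(surgery_type = o$id, config_id = j,
                                      tray_type = names(cj$trays),
                                      n = vapply(cj$trays, as.integer, integer(1),
                                                 USE.NAMES = FALSE))
    }
  }
  config_trays <- dplyr::bind_rows(ct)
  unknown <- setdiff(config_trays$tray_type, tray_types$id)
  if (length(unknown)) {
    stop("schema error: configuration references undefined tray '",
         unknown[1], "'", call. = FALSE)
  }

  defaults <- default_resources()
  workstations <- if (is.null(doc$workstations)) defaults$workstations else {
    purrr::imap_dfr(doc$workstations, function(w, i) {
      p <- paste0("workstations[", i, "]")
      check_keys(w, required = c("kind", "count", "capacity",
                                 "service_mu", "service_sigma"),
                 optional = character(), path = p)
      tibble(kind = as.character(w$kind),
             count = as.integer(num_field(w, "count", p)),
             capacity = as.integer(num_field(w, "capacity", p)),
             service_mu = num_field(w, "service_mu", p),
             service_sigma = num_field(w, "service_sigma", p))
    })
  }
  machines <- if (is.null(doc$machines)) defaults$machines else {
    purrr::imap_dfr(doc$machines, function(m, i) {
      p <- paste0("machines[", i, "]")
      check_keys(m, required = c("kind", "count", "capacity", "charge_minutes",
                                 "load_mu", "load_sigma", "start_threshold"),
                 optional = c("layers", "layer_units", "unload_mu", "unload_sigma"),
                 path = p)
      tibble(kind = as.character(m$kind),
             count = as.integer(num_field(m, "count", p)),
             capacity = as.integer(num_field(m, "capacity", p)),
             layers = as.integer(m$layers %||% NA_integer_),
             layer_units = as.integer(m$layer_units %||% NA_integer_),
             charge_minutes = num_field(m, "charge_minutes", p),
             load_mu = num_field(m, "load_mu", p),
             load_sigma = num_field(m, "load_sigma", p),
             unload_mu = as.numeric(m$unload_mu %||% NA_real_),
             unload_sigma = as.numeric(m$unload_sigma %||% NA_real_),
             start_threshold = num_field(m, "start_threshold", p))
    })
  }
  staff <- if (is.null(doc$staff)) defaults$staff_shifts else {
    purrr::imap_dfr(doc$staff, function(s, i) {
      p <- paste0("staff[", i, "]")
      check_keys(s, required = c("team", "days", "start", "end", "headcount"),
                 optional = character(), path = p)
      tibble(team = as.character(s$team),
             weekday = as.character(unlist(s$days)),
             start = parse_clock(s$start),
             end = parse_clock(s$end),
             headcount = as.integer(num_field(s, "headcount", p)))
    })
  }
  batch <- if (is.null(doc$batch_schedule)) {
    list(insertion_times = c(660, 960), batched_sources = "outpatient")
  } else {
    check_keys(doc$batch_schedule, required = character(),
               optional = c("insertion_times", "batched_sources"),
               path = "batch_schedule")
    list(insertion_times = parse_clock(unlist(doc$batch_schedule$insertion_times)),
         batched_sources = as.character(unlist(doc$batch_schedule$batched_sources)))
  }

  inst <- css_instance(
    tray_types = tray_types,
    surgery_types = dplyr::bind_rows(st),
    surgery_rates = dplyr::bind_rows(sr),
    configurations = dplyr::bind_rows(cfg),
    config_trays = config_trays,
    workstations = workstations,
    machines = machines,
    staff_shifts = staff,
    operating_rooms = as.character(unlist(doc$operating_rooms)),
    batch_schedule = batch,
    outpatient_rate = doc$outpatient_rate %||% 0,
    outpatient_window = parse_clock(unlist(doc$outpatient_window %||% c(480, 1020))),
    or_day_window = parse_clock(unlist(doc$or_day_window %||% c(480, 960))),
    size_map = size_map
  )
  assert_valid_instance(inst)
  inst
}

#' Write an instance to a YAML document
#'
#' The output is canonical: loading and re-saving a saved instance is the
#' identity on the file contents.
#'
#' @param instance A `css_instance`.
#' @param path File path; if `NULL`, the YAML text is returned invisibly.
#' @return The YAML text, invisibly.
#' @export
save_instance <- function(instance, path = NULL) {
  tt <- instance$tray_types
  doc <- list(
    size_map = as.list(setNames(as.integer(instance$size_map),
                                names(instance$size_map))),
    operating_rooms = as.list(instance$operating_rooms),
    or_day_window = as.list(instance$or_day_window),
    outpatient_rate = instance$outpatient_rate,
    outpatient_window = as.list(instance$outpatient_window),
    tray_types = purrr::pmap(
      list(tt$id, tt$size_class, tt$compat_class, tt$current_inventory, tt$source),
      function(id, sc, cc, inv, src) {
        list(id = id, size_class = sc, compat_class = cc,
             current_inventory = as.integer(inv), source = src)
      }),
    surgery_types = purrr::map(seq_len(nrow(instance$surgery_types)), function(i) {
      o <- instance$surgery_types[i, ]
      rates <- instance$surgery_rates[instance$surgery_rates$surgery_type == o$id, ]
      rates <- rates[rates$rate > 0, ]
      cfg <- instance$configurations[instance$configurations$surgery_type == o$id, ]
      list(
        id = o$id, duration_mu = o$duration_mu, duration_sigma = o$duration_sigma,
        rates = as.list(setNames(rates$rate, rates$weekday)),
        configurations = purrr::map(cfg$config_id, function(cid) {
          ctr <- instance$config_trays[
            instance$config_trays$surgery_type == o$id &
              instance$config_trays$config_id == cid, ]
          list(probability = cfg$probability[cfg$config_id == cid],
               trays = as.list(setNames(as.integer(ctr$n), ctr$tray_type)))
        })
      )
    }),
    workstations = purrr::pmap(instance$workstations, function(...) {
      w <- list(...)
      list(kind = w$kind, count = as.integer(w$count),
           capacity = as.integer(w$capacity),
           service_mu = w$service_mu, service_sigma = w$service_sigma)
    }),
    machines = purrr::pmap(instance$machines, function(...) {
      m <- list(...)
      out <- list(kind = m$kind, count = as.integer(m$count),
                  capacity = as.integer(m$capacity))
      if (!is.na(m$layers)) {
        out$layers <- as.integer(m$layers)
        out$layer_units <- as.integer(m$layer_units)
      }
      out$charge_minutes <- m$charge_minutes
      out$load_mu <- m$load_mu
      out$load_sigma <- m$load_sigma
      if (!is.na(m$unload_mu)) {
        out$unload_mu <- m$unload_mu
        out$unload_sigma <- m$unload_sigma
      }
      out$start_threshold <- m$start_threshold
      out
    }),
    staff = {
      sh <- instance$staff_shifts
      key <- paste(sh$team, sh$start, sh$end, sh$headcount, sep = "\r")
      purrr::map(unique(key), function(k) {
        rows <- sh[key == k, ]
        list(team = rows$team[1],
             days = as.list(rows$weekday),
             start = rows$start[1], end = rows$end[1],
             headcount = as.integer(rows$headcount[1]))
      })
    },
    batch_schedule = list(
      insertion_times = as.list(instance$batch_schedule$insertion_times),
      batched_sources = as.list(instance$batch_schedule$batched_sources)
    )
  )
  txt <- yaml::as.yaml(doc, precision = 12)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Reference CSS resource parameters
#'
#' Workstation, machine and staffing parameters of the mid-size reference
#' hospital: two pre-cleaning / assembly / wrapping workstations, four
#' 48-unit disinfectors with a four-layer loading rack (12 units per
#' layer, 20% start threshold), three 30-tray autoclaves (50% start
#' threshold), 60-minute machine cycles, and a three-shift weekday /
#' single-shift weekend staff roster. Lognormal manual-task parameters are
#' stored log-scale, converted from natural-scale means/sds (minutes) with
#' [lognormal_params()].
#'
#' @return List with tibbles `workstations`, `machines`, `staff_shifts`.
#' @export
default_resources <- function() {
  ln <- function(m, s) lognormal_params(m, s)
  pre <- ln(1, 1.5); asm <- ln(2, 1); wrap <- ln(0.5, 0.2)
  dlo <- ln(2, 0.3); dun <- ln(0.5, 0.2); alo <- ln(1, 0.3)
  workstations <- tibble(
    kind = c("pre_clean", "assemble", "wrap"),
    count = c(2L, 2L, 2L),
    capacity = c(1L, 1L, 1L),
    service_mu = c(pre$mu, asm$mu, wrap$mu),
    service_sigma = c(pre$sigma, asm$sigma, wrap$sigma)
  )
  machines <- tibble(
    kind = c("disinfector", "autoclave"),
    count = c(4L, 3L),
    capacity = c(48L, 30L),
    layers = c(4L, NA_integer_),
    layer_units = c(12L, NA_integer_),
    charge_minutes = c(60, 60),
    load_mu = c(dlo$mu, alo$mu),
    load_sigma = c(dlo$sigma, alo$sigma),
    unload_mu = c(dun$mu, NA_real_),
    unload_sigma = c(dun$sigma, NA_real_),
    start_threshold = c(0.20, 0.50)
  )
  wd <- weekdays_short()[1:5]
  we <- weekdays_short()[6:7]
  shift <- function(team, days, start, end, n) {
    tibble(team = team, weekday = days,
           start = parse_clock(start), end = parse_clock(end),
           headcount = as.integer(n))
  }
  staff_shifts <- dplyr::bind_rows(
    shift("pre_cleaning", wd, "7:30", "9:45", 1),
    shift("pre_cleaning", wd, "9:45", "17:00", 2),
    shift("pre_cleaning", wd, "17:00", "18:30", 1),
    shift("pre_cleaning", we, "8:00", "12:30", 1),
    shift("post_cleaning", wd, "7:30", "9:45", 6),
    shift("post_cleaning", wd, "9:45", "17:00", 9),
    shift("post_cleaning", wd, "17:00", "18:30", 3),
    shift("post_cleaning", we, "8:00", "13:00", 1)
  )
  list(workstations = workstations, machines = machines,
       staff_shifts = staff_shifts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
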