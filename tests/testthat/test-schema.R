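test_that("default registry has the full 19-label inventory with the documented attribute layout", {
  sc <- sig_schema()
  expect_length(sc$labels, 19)
  expect_setequal(names(sc$labels),
                  c("DISPENSE", "DISPENSE_UNIT", "MEDICATION", "TAKE",
                    "STRENGTH", "STRENGTH_UNIT", "DOSEAMOUNT",
                    "DOSEAMOUNT_UNIT", "DOSEFORM", "DURATION",
                    "DURATION_UNIT", "FREQ", "TIMING", "PRN", "INDICATION",
                    "ROUTE", "REFILL", "SUB_STATUS", "INSTRUCTION"))
  # span-only tags carry no attributes
  expect_length(sc$labels$PRN$attributes, 0)
  expect_length(sc$labels$INDICATION$attributes, 0)
  # FREQ: four numerics plus the unit choice
  expect_named(sc$labels$FREQ$attributes,
               c("times_per", "to_times_per", "every", "to_every", "unit"),
               ignore.order = TRUE)
  expect_equal(sc$labels$FREQ$attributes$unit$allowed_values,
               c("minute", "hour", "day", "week", "month", "other"))
  expect_named(sc$labels$TIMING$attributes,
               c("offset", "to_offset", "offset_unit", "direction", "event"),
               ignore.order = TRUE)
  expect_equal(sc$labels$TIMING$attributes$direction$allowed_values,
               c("before", "after", "other"))
  expect_named(sc$labels$ROUTE$attributes, c("route", "side"),
               ignore.order = TRUE)
  expect_equal(sc$labels$ROUTE$attributes$side$allowed_values,
               c("left", "right", "both"))
  for (lab in c("TAKE", "STRENGTH", "DOSEAMOUNT"))
    expect_named(sc$labels[[lab]]$attributes, c("amount", "to_amount"))
  expect_named(sc$labels$DURATION$attributes, c("num", "to_num"))
  expect_named(sc$labels$DISPENSE$attributes, c("quantity", "to_quantity"))
  expect_equal(sc$labels$REFILL$attributes$refill$kind, "boolean")
  expect_equal(sc$labels$SUB_STATUS$attributes$subst$kind, "boolean")
})

test_that("configurable value lists merge and invalid configs are rejected", {
  sc <- sig_schema(config = list(ROUTE = list(route = c("oral", "topical",
                                                        "other"))))
  expect_length(sc$labels$ROUTE$attributes$route$allowed_values, 3)
  # fixed lists cannot be configured; unknown names error
  expect_error(sig_schema(config = list(FREQ = list(unit = "fortnight"))),
               "not configurable")
  expect_error(sig_schema(config = list(BOGUS = list(x = "y"))),
               "unknown label")
  expect_error(sig_schema(config = list(ROUTE = list(bogus = "y"))),
               "unknown attribute")
})

test_that("registry round-trips through its on-disk form", {
  sc <- sig_schema(config = list(DOSEFORM = list(form = c("tablet", "gel",
                                                          "other"))))
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_schema(sc, path)
    expect_identical(read_schema(path), sc)
  }
})

test_that("every standard attribute name resolves within the registry", {
  idx <- rxsig:::schema_attribute_index(sig_schema())
  named <- c("form", "route", "side", "unit", "every", "to_every",
             "times_per", "to_times_per", "direction", "event", "offset",
             "to_offset", "offset_unit", "amount", "to_amount", "num",
             "to_num", "quantity", "to_quantity", "refill", "subst", "name",
             "note")
  expect_setequal(unique(idx$attribute), named)
  # within any one label, attribute names are unique
  expect_false(any(duplicated(paste(idx$label, idx$attribute))))
  # shortened aliases fold to the canonical names
  expect_equal(rxsig:::canonical_attribute_name(c("amt", "to_amt", "unit")),
               c("amount", "to_amount", "unit"))
})

test_that("validate_tag reports exactly the broken constraints", {
  sc <- sig_schema()
  ok <- tag_instance("FREQ", 5, 22, list(unit = "day", times_per = 2))
  expect_equal(nrow(validate_tag(ok, 30, sc)), 0)

  prn <- tag_instance("PRN", 0, 4, list(reason = "pain"))
  v <- validate_tag(prn, 10, sc)
  expect_equal(nrow(v), 1)
  expect_equal(v$rule, "known_attribute")

  timing <- tag_instance("TIMING", 0, 4, list(direction = "during"))
  v <- validate_tag(timing, 10, sc)
  expect_equal(nrow(v), 1)
  expect_equal(v$field, "direction")

  expect_equal(validate_tag(tag_instance("TAKE", 5, 5), 10, sc)$rule,
               "span_bounds")
  expect_equal(validate_tag(tag_instance("TAKE", 0, 11), 10, sc)$rule,
               "span_bounds")
  expect_equal(nrow(validate_tag(
    tag_instance("TAKE", 0, 2, list(amount = -1)), 10, sc)), 1)
  expect_equal(nrow(validate_tag(
    tag_instance("REFILL", 0, 2, list(refill = "yes")), 10, sc)), 1)
  expect_equal(validate_tag(tag_instance("WRONG", 0, 2), 10, sc)$rule,
               "known_label")
})

test_that("validate_document aggregates violations and warns on same-label overlap", {
  sc <- sig_schema()
  empty <- sig_document("d", "take 2 tablets")
  rep <- validate_document(empty, sc)
  expect_equal(nrow(rep$violations), 0)
  expect_length(rep$warnings, 0)

  one_ok <- sig_document("d", "take 2 tablets",
                         list(tag_instance("TAKE", 5, 6, list(amount = 2))))
  expect_equal(nrow(validate_document(one_ok, sc)$violations), 0)

  mixed <- sig_document("d", "refill twice a day", list(
    tag_instance("REFILL", 0, 6, list(refill = "maybe")),
    tag_instance("FREQ", 7, 18, list(times_per = 2, unit = "day"))))
  rep <- validate_document(mixed, sc)
  expect_equal(nrow(rep$violations), 1)
  expect_equal(rep$violations$tag, 1)

  overlapping <- sig_document("d", "take 2 tablets", list(
    tag_instance("TAKE", 5, 6), tag_instance("TAKE", 5, 14)))
  expect_length(validate_document(overlapping, sc)$warnings, 1)
})
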