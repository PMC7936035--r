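test_that("the block duplication with partial loss turns VertGO into Noto1GO", {
  go <- notoGeneOrders()
  v <- go$VertGO
  ## duplicate nad6..CoRe; copy 1 keeps the trailing T,-P,CoRe block,
  ## copy 2 survives completely
  ev <- rearrangementEvent("tdrl", segment = c("nad6", "CoRe"), order = v,
                           keep = rbind(c(FALSE, FALSE, FALSE, TRUE, TRUE,
                                          TRUE),
                                        rep(TRUE, 6)))
  expect_identical(eventKindLabel(ev), "TD-PRL")
  expect_true(ordersEqual(applyEvent(v, ev), go$Noto1GO))
})

test_that("partial random loss reproduces the named transitions", {
  go <- notoGeneOrders()
  lossTP <- rearrangementEvent("prl", drop = c("T(b)", "P(b)"),
                               order = go$Noto1GO)
  expect_true(ordersEqual(applyEvent(go$Noto1GO, lossTP), go$DissoGO))
  lossCoRe1 <- rearrangementEvent("prl", drop = "CoRe(1)",
                                  order = go$Noto2GO)
  expect_true(ordersEqual(applyEvent(go$Noto2GO, lossCoRe1), go$Noto3GO))
  ## dropping the last copy of an essential element is refused
  expect_error(applyEvent(go$VertGO,
                          rearrangementEvent("prl", drop = "cob",
                                             order = go$VertGO)),
               "every copy")
})

test_that("the long inversion turns the pre-inversion intermediate into TremaGO", {
  go <- notoGeneOrders()
  ev <- rearrangementEvent("inversion", segment = c("CoRe", "I"),
                           order = go$TremaIntGO)
  out <- applyEvent(go$TremaIntGO, ev)
  expect_true(ordersEqual(out, go$TremaGO))
  ## the block lands on the opposite strand
  labs <- orderLabels(out); signs <- orderSigns(out)
  for (g in c("CoRe", "nad1", "rrnS", "rrnL"))
    expect_identical(signs[labs == g], -1L)
  ## inversion is an involution
  ev2 <- rearrangementEvent("inversion", segment = c("I", "CoRe"),
                            order = out)
  expect_true(ordersEqual(applyEvent(out, ev2), go$TremaIntGO))
})

test_that("inversion applied twice to the same segment is the identity", {
  set.seed(21)
  for (r in 1:5) {
    o <- randomToyOrder(6)
    i <- sample(2:6, 1); j <- i + sample.int(6 - i + 1, 1) - 1L
    ev <- rearrangementEvent("inversion", segment = c(i, j))
    expect_true(ordersEqual(applyEvent(applyEvent(o, ev), ev), o))
  }
})

test_that("event validity rejects malformed duplications", {
  ## non-contiguous retained block
  expect_error(new("RearrangementEvent", kind = "tdrl", seg = c(2L, 4L),
                   at = NA_integer_, copies = 2L,
                   keep = rbind(c(TRUE, FALSE, TRUE), rep(TRUE, 3)),
                   drop = integer()) |> validObject(),
               "contiguous")
  ## a copy reduced to a single element
  expect_error(new("RearrangementEvent", kind = "tdrl", seg = c(2L, 4L),
                   at = NA_integer_, copies = 2L,
                   keep = rbind(c(TRUE, TRUE, FALSE),
                                c(FALSE, FALSE, TRUE)),
                   drop = integer()) |> validObject(),
               "at least two")
  ## an element losing every copy within the event
  expect_error(new("RearrangementEvent", kind = "tdrl", seg = c(2L, 4L),
                   at = NA_integer_, copies = 2L,
                   keep = rbind(c(TRUE, TRUE, FALSE),
                                c(TRUE, TRUE, FALSE)),
                   drop = integer()) |> validObject(),
               "every copy")
})

test_that("duplications retaining everything are labeled TD / TriD", {
  go <- notoGeneOrders()
  td <- rearrangementEvent("td", segment = c("nad6", "CoRe"),
                           order = go$Noto3GO)
  expect_identical(eventKindLabel(td), "TD")
  expect_true(ordersEqual(applyEvent(go$Noto3GO, td), go$ChamGO))
  tri <- rearrangementEvent("trid", segment = c("nad6", "E"),
                            order = go$Noto3GO)
  expect_identical(eventKindLabel(tri), "TriD")
  out <- applyEvent(go$Noto3GO, tri)
  expect_identical(sum(orderLabels(out) == "nad6"), 3L)
})

test_that("transpositions move segments with and without strand flip", {
  v <- notoGeneOrders("VertGO")[[1]]
  iT <- which(orderLabels(v) == "T")
  iN5 <- which(orderLabels(v) == "nad5")
  ev <- rearrangementEvent("transposition", segment = c(iT, iT), at = iN5)
  out <- applyEvent(v, ev)
  expect_true(ordersEqual(out, notoGeneOrders("Noto3GO")[[1]]))
  evIt <- rearrangementEvent("inverse_transposition", segment = c(iT, iT),
                             at = iN5)
  outIt <- applyEvent(v, evIt)
  labs <- orderLabels(outIt)
  expect_identical(orderSigns(outIt)[labs == "T"], -1L)
})
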