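{
  "mean_poly": [127.5, 122.5, 55],
  "beta": [206.239477846076, 100.020831163646, 23.1900361745681],
  "Omega": [
    [3459.18479843973, 1647.64996547589, 357.679453114491],
    [1647.64996547589, 839.288568954844, 193.127606559128],
    [357.679453114491, 193.127606559128, 46.9264598750696]
  ],
  "P": [
    [420.9704, 174.678016763644],
    [174.678016763644, 76.1912]
  ],
  "resid_coef": [0.169],
  "resid_floor": [15],
  "note": ["calibrated once: per-day h2 and genetic-correlation bands, plus negligible (<0.5%) positivity truncation per day; units are kilopixel-like projected shoot area"]
}
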