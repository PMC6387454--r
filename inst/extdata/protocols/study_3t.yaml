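# 3-T relaxometry protocol: DESPOT1-HIFI (2x IR-sGRE + 3x sGRE), ME-sGRE for
# R2*, and the single-slice IR-SE gold-standard series.
# Times in milliseconds (time_unit key); flip angles in degrees.
# train_length 80 = 72 slices x 1.111 slice oversampling, rounded.
name: study_3t
time_unit: ms
sequences:
  - name: irsgre_long
    kind: IR-sGRE
    tr: 1190
    te: [2.3]
    ti: 1000
    flip: 5
    echo_spacing: 4.5
    train_length: 80
  - name: irsgre_short
    kind: IR-sGRE
    tr: 632
    te: [2.3]
    ti: 450
    flip: 5
    echo_spacing: 4.5
    train_length: 80
  - name: sgre_fa12
    kind: sGRE
    tr: 5.7
    te: [2.5]
    flip: 12
  - name: sgre_fa5
    kind: sGRE
    tr: 5.7
    te: [2.5]
    flip: 5
  - name: sgre_fa3
    kind: sGRE
    tr: 5.7
    te: [2.5]
    flip: 3
  - name: mesgre
    kind: ME-sGRE
    tr: 50
    te: [4.6, 8.5, 14.0, 19.5, 25.0, 30.5, 36.0, 41.5]
    flip: 15
  - name: irse
    kind: IR-SE
    tr: 1550
    te: [11]
    ti: [30, 330, 730, 1130, 1530]
    flip: 90
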