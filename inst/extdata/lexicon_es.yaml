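# Default Spanish text-mining lexicon. Patterns are stored lower-case and
# unaccented; matching folds case and accents first.
cancer_words: [cancer, carcinoma, adenocarcinoma, neoplasia,
               neoplasia maligna, tumor maligno, neo]
organs:
  esophageal: [esofago, esofagico, esofagica, union gastroesofagica]
  gastric: [estomago, gastrico, gastrica, antro gastrico]
  pancreatic: [pancreas, pancreatico, pancreatica, cabeza de pancreas,
               cola de pancreas]
  hepatobiliary: [higado, hepatico, hepatica, hepaticas, via biliar,
                  vias biliares, vesicula biliar, hepatocelular]
  colorectal: [colon, recto, rectal, colorrectal, sigma, ciego,
               colon ascendente, colon descendente, colon transverso]
standalone:
  esophageal: []
  gastric: [linitis plastica]
  pancreatic: []
  hepatobiliary: [hepatocarcinoma, colangiocarcinoma, hepatoma, ampuloma,
                  ampulloma]
  colorectal: []
exclude:
  suspicion: [descartar, sospecha, dudoso, posible, probable,
              pendiente de confirmar, a estudio]
  screening: [cribado, screening, sangre oculta en heces]
  family_history: [antecedente familiar, antecedentes familiares,
                   madre con, padre con, hermano con, hermana con]
  negation: [no evidencia de, sin evidencia de, se descarta, negativo para,
             no se observa, sin signos de]
reassign:
  - pattern: angulo hepatico
    to: colorectal
  - pattern: union gastroesofagica|gastroesofagic
    to: esophageal
  - pattern: ampuloma|ampulloma|ampular
    to: hepatobiliary
global_exclude:
  neuroendocrine: [neuroendocrino, neuroendocrina, carcinoide]
  genetic_syndrome: [sindrome de lynch, lynch, poliposis adenomatosa familiar,
                     cancer colorrectal hereditario]
metastasis:
  hepatobiliary: [metastasis hepatica, metastasis hepaticas,
                  metastasis en higado, metastasis en el higado]
  pancreatic: [metastasis pancreatica, metastasis pancreaticas]
  gastric: [metastasis gastrica, metastasis gastricas]
  esophageal: [metastasis esofagica]
  colorectal: [metastasis colonica, metastasis colonicas]
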