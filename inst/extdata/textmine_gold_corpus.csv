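text,gold_type,gold_excluded
"neoplasia de esófago",esophageal,no
"carcinoma de esofago tercio distal",esophageal,no
"adenocarcinoma esofágico estadio III",esophageal,no
"adenocarcinoma de la unión gastroesofágica",esophageal,no
"neoplasia de cardias con extensión a la unión gastroesofágica",esophageal,no
"tumor maligno de esófago en tratamiento",esophageal,no
"cáncer gástrico avanzado",gastric,no
"adenocarcinoma de estómago",gastric,no
"neoplasia de estómago intervenida",gastric,no
"linitis plástica",gastric,no
"carcinoma de antro gástrico",gastric,no
"neo gástrica confirmada por biopsia",gastric,no
"adenocarcinoma de páncreas",pancreatic,no
"cáncer de páncreas irresecable",pancreatic,no
"neoplasia de cabeza de páncreas",pancreatic,no
"carcinoma de cola de páncreas",pancreatic,no
"tumor maligno de páncreas en quimioterapia",pancreatic,no
"hepatocarcinoma sobre cirrosis",hepatobiliary,no
"colangiocarcinoma hiliar",hepatobiliary,no
"carcinoma hepatocelular",hepatobiliary,no
"neoplasia de vía biliar",hepatobiliary,no
"cáncer de vesícula biliar",hepatobiliary,no
"ampuloma intervenido",hepatobiliary,no
"ampulloma con ictericia obstructiva",hepatobiliary,no
"neoplasia maligna de hígado",hepatobiliary,no
"adenocarcinoma de colon",colorectal,no
"cáncer de recto medio",colorectal,no
"neoplasia de sigma estenosante",colorectal,no
"carcinoma de ciego",colorectal,no
"cáncer colorrectal estadio II",colorectal,no
"neoplasia de colon ascendente",colorectal,no
"adenocarcinoma rectal en radioterapia",colorectal,no
"neoplasia en ángulo hepático del colon",colorectal,no
"carcinoma de colon transverso junto al ángulo hepático",colorectal,no
"neo de recto operada",colorectal,no
"tumor maligno de colon descendente",colorectal,no
"descartar cáncer de colon",colorectal,yes
"sospecha de neoplasia de páncreas",pancreatic,yes
"posible carcinoma gástrico, pendiente endoscopia",gastric,yes
"probable hepatocarcinoma, se solicita TAC",hepatobiliary,yes
"cribado de cáncer colorrectal",colorectal,yes
"screening de cáncer de colon con sangre oculta en heces",colorectal,yes
"antecedentes familiares de cáncer de colon",colorectal,yes
"madre con cáncer de estómago",gastric,yes
"no evidencia de neoplasia de esófago en la endoscopia",esophageal,yes
"sin evidencia de carcinoma de páncreas en TAC",pancreatic,yes
"se descarta neoplasia de recto",colorectal,yes
"colonoscopia negativo para cáncer de colon",colorectal,yes
"tumor neuroendocrino de páncreas",pancreatic,yes
"carcinoma neuroendocrino gástrico",gastric,yes
"tumor carcinoide de recto",none,yes
"síndrome de Lynch con vigilancia endoscópica",none,yes
"cáncer colorrectal hereditario no polipósico",colorectal,yes
"poliposis adenomatosa familiar",none,yes
"ampuloma neuroendocrino",hepatobiliary,yes
"control rutinario, sin hallazgos relevantes",none,no
"hipertensión arterial en tratamiento",none,no
"diabetes mellitus tipo 2",none,no
"gastritis crónica sin displasia",none,no
"pólipo de colon benigno extirpado",none,no
"hemorroides externas",none,no
"esofagitis péptica grado B",none,no
"pancreatitis aguda de origen biliar",none,no
"hepatopatía crónica sin lesiones focales",none,no
"cáncer de recto con metástasis hepáticas",colorectal,no
"neoplasia de colon con metástasis en hígado",colorectal,no
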