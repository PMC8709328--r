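{
  "cirrhotic|washout|hyper-enhancement": "HCC",
  "noncirrhotic|washout|hyper-enhancement": "adenoma",
  "cirrhotic|washout|rim enhancement": "metastasis",
  "noncirrhotic|washout|rim enhancement": "metastasis",
  "cirrhotic|washout|rim-like with central hypo-enhancement": "cholangiocarcinoma",
  "noncirrhotic|washout|rim-like with central hypo-enhancement": "cholangiocarcinoma",
  "cirrhotic|nowashout|peripheral nodular enhancement": "haemangioma",
  "noncirrhotic|nowashout|peripheral nodular enhancement": "haemangioma",
  "cirrhotic|nowashout|centrifugal hyper-enhancement": "FNH",
  "noncirrhotic|nowashout|centrifugal hyper-enhancement": "FNH",
  "cirrhotic|nowashout|peripheral enhancement with septa": "abscess",
  "noncirrhotic|nowashout|peripheral enhancement with septa": "abscess",
  "cirrhotic|nowashout|iso-enhancement": "regenerative nodule",
  "noncirrhotic|nowashout|iso-enhancement": "focal fatty alteration"
}
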