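# Candidate bioactive lipid species: annotations of the 42 lipids enriched
# both upon ELOVL1 or SLC27A1 knockdown and upon suspension-induced
# differentiation of primary human keratinocytes (one annotation per line).
# siELOVL1 intersection set (26 species)
Ceramide - 32:1:2 (C14:0 Cer)
Ceramide - 34:1:2 (C16:0 Cer)
Ceramide - 34:2:2 (C16:1 Cer)
Ceramide - 38:1:2 (C20:0 Cer)
Ceramide - 40:1:2 (C22:0 Cer)
Ceramide - 40:2:2 (C22:1 Cer)
Hexosylceramide - 34:1:2 (C16:0 HexCer)
Hexosylceramide - 36:1:2 (C18:0 HexCer)
Hexosylceramide - 38:1:2 (C20:0 HexCer)
Hexosylceramide - 40:1:2 (C22:0 HexCer)
Hexosylceramide - 40:2:2 (C22:1 HexCer)
Phosphatidylcholine - 17:0:0;17:1:0
Phosphatidylcholine - 18:0:0;18:1:0
Phosphatidylcholine - 18:0:0;18:2:0
Phosphatidylcholine - 18:1:0;18:1:0
Phosphatidylcholine - 18:1:0;18:2:0
Phosphatidylcholine - 18:2:0;18:2:0
Phosphatidylethanolamine ether - 18:1:0;18:1:0
Phosphatidylethanolamine ether - 18:1:0;20:3:0
Phosphatidylethanolamine ether - 18:1:0;20:4:0
Phosphatidylinositol - 16:1:0;20:4:0
Phosphatidylserine - 14:0:0;18:1:0
Phosphatidylserine - 16:1:0;20:0:0
Phosphatidylserine - 18:1:0;20:0:0
Phosphatidylserine - 18:2:0;20:0:0
Phosphatidylserine - 18:2:0;22:1:0
# siSLC27A1 intersection set (16 species)
Hexosylceramide - 42:2:2 (C24:1 HexCer)
Phosphatidic acid - 16:0:0;18:2:0
Phosphatidylcholine - 16:1:0;16:1:0
Phosphatidylcholine - 18:0:0;20:3:0
Phosphatidylcholine ether - 16:1:0;16:1:0
Phosphatidylcholine ether - 16:1:0;20:4:0
Phosphatidylcholine ether - 18:1:0;16:1:0
Phosphatidylcholine ether - 18:1:0;20:4:0
Phosphatidylethanolamine ether - 16:1:0;20:3:0
Phosphatidylglycerol - 16:1:0;18:0:0
Phosphatidylglycerol - 18:2:0;18:2:0
Phosphatidylglycerol - 18:2:0;20:3:0
Phosphatidylinositol - 16:2:0;18:0:0
Phosphatidylinositol - 18:2:0;20:2:0
Phosphatidylserine - 16:1:0;18:1:0
Phosphatidylserine - 18:0:0;19:1:0
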