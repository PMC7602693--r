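#NEXUS
[Published 43-taxon block of characters 1-18 of the 72-character Isodacrys
 data matrix. "?" missing, "-" inapplicable, "[..]" polymorphism.
 Characters 3 and 15 are additive.]

BEGIN DATA;
  DIMENSIONS NTAX=43 NCHAR=18;
  FORMAT DATATYPE=STANDARD SYMBOLS="0123456789" MISSING=? GAP=-;
  MATRIX
    Megalostylus_albicans         0000000---000000--
    Platyaspistes_prasinus        0010000---000000--
    Hadromeropsis_brevicoma       1010000---100100--
    Minyomerus_microps            2010001000001010--
    Minyomerus_laticeps           2010001000001010--
    Pandeleteius_hilaris          0112-11100101110--
    Pandeleteius_rotundicollis    0110011010100110--
    Pandeleteius_inflatus         0112-1110010011001
    Scalaventer_cyrillae          012011101100112121
    Scalaventer_jamaicensis       012011101100112021
    Scalaventer_subtropicus       012011101100112121
    Paululusus_hispaniole         012011121100112010
    Paululusus_constanzae         012011121100112010
    Isodrusus_debilis             1111-1120000014122
    Isodrusus_guajavus            0121-1120000114122
    aff._Isodrusus_sp.            011011120000113122
    Pandeleteinus_submetallicus   111000120010012020
    Pandeleteinus_subcancer       111001120000112121
    Pandeleteinus_elytroplanatus  111001120010012120
    aff._Pandeleteinus_sp.        011011120000113122
    Paradacrys_ensiformis         011011120100113021
    Isodillex_minutum             011011120000012112
    Isodillex_plumosum            011011120000012112
    Isodacrys_antrum              111011120001013122
    Isodacrys_apicale             111011120000112110
    Isodacrys_brevirostre         [01]11011120001012111
    Isodacrys_buchanani           111011120000112121
    Isodacrys_burkei              111011120100012120
    Isodacrys_carlae              111011120000012120
    Isodacrys_confusum            111011120000012120
    Isodacrys_crispum             111011120000013121
    Isodacrys_ellipticum          111011120100112111
    Isodacrys_fasciatum           111011120000012120
    Isodacrys_frontalis           111011120001112110
    Isodacrys_geminatum           111011120001013112
    Isodacrys_guatemalenum        111011120100112111
    Isodacrys_kuchii              111011120000112121
    Isodacrys_mexicanum           111011120000112110
    Isodacrys_obrienorum          011011120001113122
    Isodacrys_okuiltontli         111011120000112112
    Isodacrys_orizabae            111011120000012110
    Isodacrys_ovipennis           111011120100112110
    Isodacrys_schwarzi            111???120000?12120
  ;
END;

BEGIN ASSUMPTIONS;
  TYPESET * default = ord: 3 15;
END;
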