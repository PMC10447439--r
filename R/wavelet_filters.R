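# Two-channel filter banks for the supported wavelet families.
# Standard published coefficients (Daubechies, symlet, coiflet and
# biorthogonal spline banks); dec_* are analysis filters, rec_* synthesis.
# Do not edit by hand.

.wavelet_filter_banks <- list(
  "haar" = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476)
  ),
  "db2" = list(
    dec_lo = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.8365163037378079, -0.2241438680420134, -0.12940952255126037),
    rec_lo = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134, -0.12940952255126037),
    rec_hi = c(-0.12940952255126037, -0.2241438680420134, 0.8365163037378079, -0.48296291314453416)
  ),
  "db4" = list(
    dec_lo = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764, -0.18703481171909309, -0.027983769416859854, 0.6308807679298589, 0.7148465705529157, 0.2303778133088965),
    dec_hi = c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589, -0.027983769416859854, 0.18703481171909309, 0.030841381835560764, -0.0328830116668852, -0.010597401785069032),
    rec_lo = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589, -0.027983769416859854, -0.18703481171909309, 0.030841381835560764, 0.0328830116668852, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.0328830116668852, 0.030841381835560764, 0.18703481171909309, -0.027983769416859854, -0.6308807679298589, 0.7148465705529157, -0.2303778133088965)
  ),
  "db5" = list(
    dec_lo = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274, 0.07757149384004572, -0.032244869584638375, -0.24229488706638203, 0.13842814590132074, 0.7243085284377729, 0.6038292697971896, 0.16010239797419293),
    dec_hi = c(-0.16010239797419293, 0.6038292697971896, -0.7243085284377729, 0.13842814590132074, 0.24229488706638203, -0.032244869584638375, -0.07757149384004572, -0.006241490212798274, 0.012580751999081999, 0.0033357252854737712),
    rec_lo = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729, 0.13842814590132074, -0.24229488706638203, -0.032244869584638375, 0.07757149384004572, -0.006241490212798274, -0.012580751999081999, 0.0033357252854737712),
    rec_hi = c(0.0033357252854737712, 0.012580751999081999, -0.006241490212798274, -0.07757149384004572, -0.032244869584638375, 0.24229488706638203, 0.13842814590132074, -0.7243085284377729, 0.6038292697971896, -0.16010239797419293)
  ),
  "db6" = list(
    dec_lo = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961, -0.03158203931748603, 0.027522865530305727, 0.09750160558732304, -0.12976686756726194, -0.22626469396543983, 0.31525035170919763, 0.7511339080210954, 0.49462389039845306, 0.11154074335010947),
    dec_hi = c(-0.11154074335010947, 0.49462389039845306, -0.7511339080210954, 0.31525035170919763, 0.22626469396543983, -0.12976686756726194, -0.09750160558732304, 0.027522865530305727, 0.03158203931748603, 0.0005538422011614961, -0.004777257510945511, -0.0010773010853084796),
    rec_lo = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954, 0.31525035170919763, -0.22626469396543983, -0.12976686756726194, 0.09750160558732304, 0.027522865530305727, -0.03158203931748603, 0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
    rec_hi = c(-0.0010773010853084796, -0.004777257510945511, 0.0005538422011614961, 0.03158203931748603, 0.027522865530305727, -0.09750160558732304, -0.12976686756726194, 0.22626469396543983, 0.31525035170919763, -0.7511339080210954, 0.49462389039845306, -0.11154074335010947)
  ),
  "db7" = list(
    dec_lo = c(0.00035371379997452024, -0.0018016407040474908, 0.0004295779729213665, 0.01255099855609984, -0.01657454163066688, -0.03802993693501441, 0.08061260915108308, 0.07130921926683026, -0.22403618499387498, -0.14390600392856498, 0.4697822874051931, 0.7291320908462351, 0.3965393194819173, 0.07785205408500918),
    dec_hi = c(-0.07785205408500918, 0.3965393194819173, -0.7291320908462351, 0.4697822874051931, 0.14390600392856498, -0.22403618499387498, -0.07130921926683026, 0.08061260915108308, 0.03802993693501441, -0.01657454163066688, -0.01255099855609984, 0.0004295779729213665, 0.0018016407040474908, 0.00035371379997452024),
    rec_lo = c(0.07785205408500918, 0.3965393194819173, 0.7291320908462351, 0.4697822874051931, -0.14390600392856498, -0.22403618499387498, 0.07130921926683026, 0.08061260915108308, -0.03802993693501441, -0.01657454163066688, 0.01255099855609984, 0.0004295779729213665, -0.0018016407040474908, 0.00035371379997452024),
    rec_hi = c(0.00035371379997452024, 0.0018016407040474908, 0.0004295779729213665, -0.01255099855609984, -0.01657454163066688, 0.03802993693501441, 0.08061260915108308, -0.07130921926683026, -0.22403618499387498, 0.14390600392856498, 0.4697822874051931, -0.7291320908462351, 0.3965393194819173, -0.07785205408500918)
  ),
  "sym5" = list(
    dec_lo = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094, 0.1993975339773936, 0.7234076904024206, 0.6339789634582119, 0.01660210576452232, -0.17532808990845047, -0.021101834024758855, 0.019538882735286728),
    dec_hi = c(-0.019538882735286728, -0.021101834024758855, 0.17532808990845047, 0.01660210576452232, -0.6339789634582119, 0.7234076904024206, -0.1993975339773936, -0.039134249302383094, -0.029519490925774643, 0.027333068345077982),
    rec_lo = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047, 0.01660210576452232, 0.6339789634582119, 0.7234076904024206, 0.1993975339773936, -0.039134249302383094, 0.029519490925774643, 0.027333068345077982),
    rec_hi = c(0.027333068345077982, -0.029519490925774643, -0.039134249302383094, -0.1993975339773936, 0.7234076904024206, -0.6339789634582119, 0.01660210576452232, 0.17532808990845047, -0.021101834024758855, -0.019538882735286728)
  ),
  "sym6" = list(
    dec_lo = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057, -0.048311742585633, 0.4910559419267466, 0.787641141030194, 0.3379294217276218, -0.07263752278646252, -0.021060292512300564, 0.04472490177066578, 0.0017677118642428036, -0.007800708325034148),
    dec_hi = c(0.007800708325034148, 0.0017677118642428036, -0.04472490177066578, -0.021060292512300564, 0.07263752278646252, 0.3379294217276218, -0.787641141030194, 0.4910559419267466, 0.048311742585633, -0.11799011114819057, -0.0034907120842174702, 0.015404109327027373),
    rec_lo = c(-0.007800708325034148, 0.0017677118642428036, 0.04472490177066578, -0.021060292512300564, -0.07263752278646252, 0.3379294217276218, 0.787641141030194, 0.4910559419267466, -0.048311742585633, -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
    rec_hi = c(0.015404109327027373, -0.0034907120842174702, -0.11799011114819057, 0.048311742585633, 0.4910559419267466, -0.787641141030194, 0.3379294217276218, 0.07263752278646252, -0.021060292512300564, -0.04472490177066578, 0.0017677118642428036, 0.007800708325034148)
  ),
  "sym7" = list(
    dec_lo = c(0.002681814568257878, -0.0010473848886829163, -0.01263630340325193, 0.03051551316596357, 0.0678926935013727, -0.049552834937127255, 0.017441255086855827, 0.5361019170917628, 0.767764317003164, 0.2886296317515146, -0.14004724044296152, -0.10780823770381774, 0.004010244871533663, 0.010268176708511255),
    dec_hi = c(-0.010268176708511255, 0.004010244871533663, 0.10780823770381774, -0.14004724044296152, -0.2886296317515146, 0.767764317003164, -0.5361019170917628, 0.017441255086855827, 0.049552834937127255, 0.0678926935013727, -0.03051551316596357, -0.01263630340325193, 0.0010473848886829163, 0.002681814568257878),
    rec_lo = c(0.010268176708511255, 0.004010244871533663, -0.10780823770381774, -0.14004724044296152, 0.2886296317515146, 0.767764317003164, 0.5361019170917628, 0.017441255086855827, -0.049552834937127255, 0.0678926935013727, 0.03051551316596357, -0.01263630340325193, -0.0010473848886829163, 0.002681814568257878),
    rec_hi = c(0.002681814568257878, 0.0010473848886829163, -0.01263630340325193, -0.03051551316596357, 0.0678926935013727, 0.049552834937127255, 0.017441255086855827, -0.5361019170917628, 0.767764317003164, -0.2886296317515146, -0.14004724044296152, 0.10780823770381774, 0.004010244871533663, -0.010268176708511255)
  ),
  "sym8" = list(
    dec_lo = c(-0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298, 0.007607487324917605, -0.1432942383508097, -0.061273359067658524, 0.4813596512583722, 0.7771857517005235, 0.3644418948353314, -0.05194583810770904, -0.027219029917056003, 0.049137179673607506, 0.003808752013890615, -0.01495225833704823, -0.0003029205147213668, 0.0018899503327594609),
    dec_hi = c(-0.0018899503327594609, -0.0003029205147213668, 0.01495225833704823, 0.003808752013890615, -0.049137179673607506, -0.027219029917056003, 0.05194583810770904, 0.3644418948353314, -0.7771857517005235, 0.4813596512583722, 0.061273359067658524, -0.1432942383508097, -0.007607487324917605, 0.03169508781149298, 0.0005421323317911481, -0.0033824159510061256),
    rec_lo = c(0.0018899503327594609, -0.0003029205147213668, -0.01495225833704823, 0.003808752013890615, 0.049137179673607506, -0.027219029917056003, -0.05194583810770904, 0.3644418948353314, 0.7771857517005235, 0.4813596512583722, -0.061273359067658524, -0.1432942383508097, 0.007607487324917605, 0.03169508781149298, -0.0005421323317911481, -0.0033824159510061256),
    rec_hi = c(-0.0033824159510061256, 0.0005421323317911481, 0.03169508781149298, -0.007607487324917605, -0.1432942383508097, 0.061273359067658524, 0.4813596512583722, -0.7771857517005235, 0.3644418948353314, 0.05194583810770904, -0.027219029917056003, -0.049137179673607506, 0.003808752013890615, 0.01495225833704823, -0.0003029205147213668, -0.0018899503327594609)
  ),
  "bior1.3" = list(
    dec_lo = c(-0.08838834764831845, 0.08838834764831845, 0.7071067811865476, 0.7071067811865476, 0.08838834764831845, -0.08838834764831845),
    dec_hi = c(-0.0, 0.0, -0.7071067811865476, 0.7071067811865476, -0.0, 0.0),
    rec_lo = c(0.0, 0.0, 0.7071067811865476, 0.7071067811865476, 0.0, 0.0),
    rec_hi = c(-0.08838834764831845, -0.08838834764831845, 0.7071067811865476, -0.7071067811865476, 0.08838834764831845, 0.08838834764831845)
  ),
  "bior3.5" = list(
    dec_lo = c(-0.013810679320049757, 0.04143203796014927, 0.052480581416189075, -0.26792717880896527, -0.07181553246425873, 0.966747552403483, 0.966747552403483, -0.07181553246425873, -0.26792717880896527, 0.052480581416189075, 0.04143203796014927, -0.013810679320049757),
    dec_hi = c(-0.0, 0.0, -0.0, 0.0, -0.1767766952966369, 0.5303300858899106, -0.5303300858899106, 0.1767766952966369, -0.0, 0.0, -0.0, 0.0),
    rec_lo = c(0.0, 0.0, 0.0, 0.0, 0.1767766952966369, 0.5303300858899106, 0.5303300858899106, 0.1767766952966369, 0.0, 0.0, 0.0, 0.0),
    rec_hi = c(-0.013810679320049757, -0.04143203796014927, 0.052480581416189075, 0.26792717880896527, -0.07181553246425873, -0.966747552403483, 0.966747552403483, 0.07181553246425873, -0.26792717880896527, -0.052480581416189075, 0.04143203796014927, 0.013810679320049757)
  ),
  "bior6.8" = list(
    dec_lo = c(0.0, 0.0019088317364812906, -0.0019142861290887667, -0.016990639867602342, 0.01193456527972926, 0.04973290349094079, -0.07726317316720414, -0.09405920349573646, 0.4207962846098268, 0.8259229974584023, 0.4207962846098268, -0.09405920349573646, -0.07726317316720414, 0.04973290349094079, 0.01193456527972926, -0.016990639867602342, -0.0019142861290887667, 0.0019088317364812906),
    dec_hi = c(-0.0, 0.0, -0.0, 0.014426282505624435, -0.014467504896790148, -0.07872200106262882, 0.04036797903033992, 0.41784910915027457, -0.7589077294536541, 0.41784910915027457, 0.04036797903033992, -0.07872200106262882, -0.014467504896790148, 0.014426282505624435, -0.0, 0.0, -0.0, 0.0),
    rec_lo = c(0.0, 0.0, 0.0, 0.014426282505624435, 0.014467504896790148, -0.07872200106262882, -0.04036797903033992, 0.41784910915027457, 0.7589077294536541, 0.41784910915027457, -0.04036797903033992, -0.07872200106262882, 0.014467504896790148, 0.014426282505624435, 0.0, 0.0, 0.0, 0.0),
    rec_hi = c(0.0, -0.0019088317364812906, -0.0019142861290887667, 0.016990639867602342, 0.01193456527972926, -0.04973290349094079, -0.07726317316720414, 0.09405920349573646, 0.4207962846098268, -0.8259229974584023, 0.4207962846098268, 0.09405920349573646, -0.07726317316720414, -0.04973290349094079, 0.01193456527972926, 0.016990639867602342, -0.0019142861290887667, -0.0019088317364812906)
  ),
  "coif5" = list(
    dec_lo = c(-9.604010112767894e-08, -1.6237995172048338e-07, 2.0612203985788783e-06, 3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05, 0.00014035632812373243, 0.0003018579416682448, -0.0006375589261258812, -0.0016616273039298788, 0.0024315754425382886, 0.006761520220620417, -0.009159507338676163, -0.019758391600965465, 0.032674799467057355, 0.041287530472117834, -0.10556315130733723, -0.06203775157498196, 0.4379823066591634, 0.7742936228603274, 0.42157126673075435, -0.052046670253554764, -0.09192158806008609, 0.028169744270532353, 0.023408322118927783, -0.010131584846900276, -0.00415931262757864, 0.0021782943778456947, 0.0003585777411617577, -0.000212081862067494),
    dec_hi = c(0.000212081862067494, 0.0003585777411617577, -0.0021782943778456947, -0.00415931262757864, 0.010131584846900276, 0.023408322118927783, -0.028169744270532353, -0.09192158806008609, 0.052046670253554764, 0.42157126673075435, -0.7742936228603274, 0.4379823066591634, 0.06203775157498196, -0.10556315130733723, -0.041287530472117834, 0.032674799467057355, 0.019758391600965465, -0.009159507338676163, -0.006761520220620417, 0.0024315754425382886, 0.0016616273039298788, -0.0006375589261258812, -0.0003018579416682448, 0.00014035632812373243, 4.12198619242655e-05, -2.1270221672515614e-05, -3.7007277113394796e-06, 2.0612203985788783e-06, 1.6237995172048338e-07, -9.604010112767894e-08),
    rec_lo = c(-0.000212081862067494, 0.0003585777411617577, 0.0021782943778456947, -0.00415931262757864, -0.010131584846900276, 0.023408322118927783, 0.028169744270532353, -0.09192158806008609, -0.052046670253554764, 0.42157126673075435, 0.7742936228603274, 0.4379823066591634, -0.06203775157498196, -0.10556315130733723, 0.041287530472117834, 0.032674799467057355, -0.019758391600965465, -0.009159507338676163, 0.006761520220620417, 0.0024315754425382886, -0.0016616273039298788, -0.0006375589261258812, 0.0003018579416682448, 0.00014035632812373243, -4.12198619242655e-05, -2.1270221672515614e-05, 3.7007277113394796e-06, 2.0612203985788783e-06, -1.6237995172048338e-07, -9.604010112767894e-08),
    rec_hi = c(-9.604010112767894e-08, 1.6237995172048338e-07, 2.0612203985788783e-06, -3.7007277113394796e-06, -2.1270221672515614e-05, 4.12198619242655e-05, 0.00014035632812373243, -0.0003018579416682448, -0.0006375589261258812, 0.0016616273039298788, 0.0024315754425382886, -0.006761520220620417, -0.009159507338676163, 0.019758391600965465, 0.032674799467057355, -0.041287530472117834, -0.10556315130733723, 0.06203775157498196, 0.4379823066591634, -0.7742936228603274, 0.42157126673075435, 0.052046670253554764, -0.09192158806008609, -0.028169744270532353, 0.023408322118927783, 0.010131584846900276, -0.00415931262757864, -0.0021782943778456947, 0.0003585777411617577, 0.000212081862067494)
  )
)

#' Supported wavelet families
#'
#' Names of the discrete wavelet families available to [dwt_denoise()] and
#' [compare_wavelets()].
#'
#' @return Character vector of family names.
#' @export
wavelet_families <- function() names(.wavelet_filter_banks)
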