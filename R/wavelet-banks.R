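# Filter banks for the supported discrete wavelets (standard published
# coefficients for the Daubechies, symlet and biorthogonal spline families).
# dec_* are analysis filters, rec_* synthesis filters; lowpass/highpass pairs.

.wavelet_banks <- list(
  "db2" = list(
    dec_lo = c(
      -0.12940952255126037, 0.2241438680420134, 0.8365163037378079, 0.48296291314453416),
    dec_hi = c(
      -0.48296291314453416, 0.8365163037378079, -0.2241438680420134, -0.12940952255126037),
    rec_lo = c(
      0.48296291314453416, 0.8365163037378079, 0.2241438680420134, -0.12940952255126037),
    rec_hi = c(
      -0.12940952255126037, -0.2241438680420134, 0.8365163037378079, -0.48296291314453416)
  ),
  "db4" = list(
    dec_lo = c(
      -0.010597401785069032, 0.0328830116668852, 0.030841381835560764, -0.18703481171909309,
      -0.027983769416859854, 0.6308807679298589, 0.7148465705529157, 0.2303778133088965),
    dec_hi = c(
      -0.2303778133088965, 0.7148465705529157, -0.6308807679298589, -0.027983769416859854,
      0.18703481171909309, 0.030841381835560764, -0.0328830116668852, -0.010597401785069032),
    rec_lo = c(
      0.2303778133088965, 0.7148465705529157, 0.6308807679298589, -0.027983769416859854,
      -0.18703481171909309, 0.030841381835560764, 0.0328830116668852, -0.010597401785069032),
    rec_hi = c(
      -0.010597401785069032, -0.0328830116668852, 0.030841381835560764, 0.18703481171909309,
      -0.027983769416859854, -0.6308807679298589, 0.7148465705529157, -0.2303778133088965)
  ),
  "db6" = list(
    dec_lo = c(
      -0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
      -0.03158203931748603, 0.027522865530305727, 0.09750160558732304, -0.12976686756726194,
      -0.22626469396543983, 0.31525035170919763, 0.7511339080210954, 0.49462389039845306,
      0.11154074335010947),
    dec_hi = c(
      -0.11154074335010947, 0.49462389039845306, -0.7511339080210954, 0.31525035170919763,
      0.22626469396543983, -0.12976686756726194, -0.09750160558732304, 0.027522865530305727,
      0.03158203931748603, 0.0005538422011614961, -0.004777257510945511,
      -0.0010773010853084796),
    rec_lo = c(
      0.11154074335010947, 0.49462389039845306, 0.7511339080210954, 0.31525035170919763,
      -0.22626469396543983, -0.12976686756726194, 0.09750160558732304, 0.027522865530305727,
      -0.03158203931748603, 0.0005538422011614961, 0.004777257510945511,
      -0.0010773010853084796),
    rec_hi = c(
      -0.0010773010853084796, -0.004777257510945511, 0.0005538422011614961,
      0.03158203931748603, 0.027522865530305727, -0.09750160558732304, -0.12976686756726194,
      0.22626469396543983, 0.31525035170919763, -0.7511339080210954, 0.49462389039845306,
      -0.11154074335010947)
  ),
  "db8" = list(
    dec_lo = c(
      -0.00011747678412476953, 0.0006754494064505693, -0.00039174037337694705,
      -0.004870352993451574, 0.008746094047405777, 0.013981027917398282, -0.044088253930794755,
      -0.017369301001807547, 0.12874742662047847, 0.0004724845739132828, -0.2840155429615469,
      -0.015829105256349306, 0.5853546836542067, 0.6756307362972898, 0.31287159091429995,
      0.05441584224310401),
    dec_hi = c(
      -0.05441584224310401, 0.31287159091429995, -0.6756307362972898, 0.5853546836542067,
      0.015829105256349306, -0.2840155429615469, -0.0004724845739132828, 0.12874742662047847,
      0.017369301001807547, -0.044088253930794755, -0.013981027917398282, 0.008746094047405777,
      0.004870352993451574, -0.00039174037337694705, -0.0006754494064505693,
      -0.00011747678412476953),
    rec_lo = c(
      0.05441584224310401, 0.31287159091429995, 0.6756307362972898, 0.5853546836542067,
      -0.015829105256349306, -0.2840155429615469, 0.0004724845739132828, 0.12874742662047847,
      -0.017369301001807547, -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
      -0.004870352993451574, -0.00039174037337694705, 0.0006754494064505693,
      -0.00011747678412476953),
    rec_hi = c(
      -0.00011747678412476953, -0.0006754494064505693, -0.00039174037337694705,
      0.004870352993451574, 0.008746094047405777, -0.013981027917398282, -0.044088253930794755,
      0.017369301001807547, 0.12874742662047847, -0.0004724845739132828, -0.2840155429615469,
      0.015829105256349306, 0.5853546836542067, -0.6756307362972898, 0.31287159091429995,
      -0.05441584224310401)
  ),
  "sym4" = list(
    dec_lo = c(
      -0.07576571478927333, -0.02963552764599851, 0.49761866763201545, 0.8037387518059161,
      0.29785779560527736, -0.09921954357684722, -0.012603967262037833, 0.0322231006040427),
    dec_hi = c(
      -0.0322231006040427, -0.012603967262037833, 0.09921954357684722, 0.29785779560527736,
      -0.8037387518059161, 0.49761866763201545, 0.02963552764599851, -0.07576571478927333),
    rec_lo = c(
      0.0322231006040427, -0.012603967262037833, -0.09921954357684722, 0.29785779560527736,
      0.8037387518059161, 0.49761866763201545, -0.02963552764599851, -0.07576571478927333),
    rec_hi = c(
      -0.07576571478927333, 0.02963552764599851, 0.49761866763201545, -0.8037387518059161,
      0.29785779560527736, 0.09921954357684722, -0.012603967262037833, -0.0322231006040427)
  ),
  "sym6" = list(
    dec_lo = c(
      0.015404109327027373, 0.0034907120842174702, -0.11799011114819057, -0.048311742585633,
      0.4910559419267466, 0.787641141030194, 0.3379294217276218, -0.07263752278646252,
      -0.021060292512300564, 0.04472490177066578, 0.0017677118642428036, -0.007800708325034148),
    dec_hi = c(
      0.007800708325034148, 0.0017677118642428036, -0.04472490177066578, -0.021060292512300564,
      0.07263752278646252, 0.3379294217276218, -0.787641141030194, 0.4910559419267466,
      0.048311742585633, -0.11799011114819057, -0.0034907120842174702, 0.015404109327027373),
    rec_lo = c(
      -0.007800708325034148, 0.0017677118642428036, 0.04472490177066578, -0.021060292512300564,
      -0.07263752278646252, 0.3379294217276218, 0.787641141030194, 0.4910559419267466,
      -0.048311742585633, -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
    rec_hi = c(
      0.015404109327027373, -0.0034907120842174702, -0.11799011114819057, 0.048311742585633,
      0.4910559419267466, -0.787641141030194, 0.3379294217276218, 0.07263752278646252,
      -0.021060292512300564, -0.04472490177066578, 0.0017677118642428036, 0.007800708325034148)
  ),
  "sym8" = list(
    dec_lo = c(
      -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
      0.007607487324917605, -0.1432942383508097, -0.061273359067658524, 0.4813596512583722,
      0.7771857517005235, 0.3644418948353314, -0.05194583810770904, -0.027219029917056003,
      0.049137179673607506, 0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
      0.0018899503327594609),
    dec_hi = c(
      -0.0018899503327594609, -0.0003029205147213668, 0.01495225833704823,
      0.003808752013890615, -0.049137179673607506, -0.027219029917056003, 0.05194583810770904,
      0.3644418948353314, -0.7771857517005235, 0.4813596512583722, 0.061273359067658524,
      -0.1432942383508097, -0.007607487324917605, 0.03169508781149298, 0.0005421323317911481,
      -0.0033824159510061256),
    rec_lo = c(
      0.0018899503327594609, -0.0003029205147213668, -0.01495225833704823,
      0.003808752013890615, 0.049137179673607506, -0.027219029917056003, -0.05194583810770904,
      0.3644418948353314, 0.7771857517005235, 0.4813596512583722, -0.061273359067658524,
      -0.1432942383508097, 0.007607487324917605, 0.03169508781149298, -0.0005421323317911481,
      -0.0033824159510061256),
    rec_hi = c(
      -0.0033824159510061256, 0.0005421323317911481, 0.03169508781149298,
      -0.007607487324917605, -0.1432942383508097, 0.061273359067658524, 0.4813596512583722,
      -0.7771857517005235, 0.3644418948353314, 0.05194583810770904, -0.027219029917056003,
      -0.049137179673607506, 0.003808752013890615, 0.01495225833704823, -0.0003029205147213668,
      -0.0018899503327594609)
  ),
  "bior2.6" = list(
    dec_lo = c(
      0.0, -0.006905339660024878, 0.013810679320049757, 0.04695630968816917,
      -0.1077232986963881, -0.16987135563661201, 0.4474660099696121, 0.966747552403483,
      0.4474660099696121, -0.16987135563661201, -0.1077232986963881, 0.04695630968816917,
      0.013810679320049757, -0.006905339660024878),
    dec_hi = c(
      -0.0, 0.0, -0.0, 0.0, -0.0, 0.3535533905932738, -0.7071067811865476, 0.3535533905932738,
      -0.0, 0.0, -0.0, 0.0, -0.0, 0.0),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.3535533905932738, 0.7071067811865476, 0.3535533905932738, 0.0,
      0.0, 0.0, 0.0, 0.0, 0.0),
    rec_hi = c(
      0.0, 0.006905339660024878, 0.013810679320049757, -0.04695630968816917,
      -0.1077232986963881, 0.16987135563661201, 0.4474660099696121, -0.966747552403483,
      0.4474660099696121, 0.16987135563661201, -0.1077232986963881, -0.04695630968816917,
      0.013810679320049757, 0.006905339660024878)
  ),
  "bior3.9" = list(
    dec_lo = c(
      -0.0006797443727836989, 0.002039233118351097, 0.005060319219611981,
      -0.020618912641105536, -0.014112787930175844, 0.09913478249423216, 0.012300136269419315,
      -0.32019196836077857, 0.0020500227115698858, 0.9421257006782068, 0.9421257006782068,
      0.0020500227115698858, -0.32019196836077857, 0.012300136269419315, 0.09913478249423216,
      -0.014112787930175844, -0.020618912641105536, 0.005060319219611981, 0.002039233118351097,
      -0.0006797443727836989),
    dec_hi = c(
      -0.0, 0.0, -0.0, 0.0, -0.0, 0.0, -0.0, 0.0, -0.1767766952966369, 0.5303300858899106,
      -0.5303300858899106, 0.1767766952966369, -0.0, 0.0, -0.0, 0.0, -0.0, 0.0, -0.0, 0.0),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.1767766952966369, 0.5303300858899106,
      0.5303300858899106, 0.1767766952966369, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    rec_hi = c(
      -0.0006797443727836989, -0.002039233118351097, 0.005060319219611981,
      0.020618912641105536, -0.014112787930175844, -0.09913478249423216, 0.012300136269419315,
      0.32019196836077857, 0.0020500227115698858, -0.9421257006782068, 0.9421257006782068,
      -0.0020500227115698858, -0.32019196836077857, -0.012300136269419315, 0.09913478249423216,
      0.014112787930175844, -0.020618912641105536, -0.005060319219611981, 0.002039233118351097,
      0.0006797443727836989)
  ),
  "bior6.8" = list(
    dec_lo = c(
      0.0, 0.0019088317364812906, -0.0019142861290887667, -0.016990639867602342,
      0.01193456527972926, 0.04973290349094079, -0.07726317316720414, -0.09405920349573646,
      0.4207962846098268, 0.8259229974584023, 0.4207962846098268, -0.09405920349573646,
      -0.07726317316720414, 0.04973290349094079, 0.01193456527972926, -0.016990639867602342,
      -0.0019142861290887667, 0.0019088317364812906),
    dec_hi = c(
      -0.0, 0.0, -0.0, 0.014426282505624435, -0.014467504896790148, -0.07872200106262882,
      0.04036797903033992, 0.41784910915027457, -0.7589077294536541, 0.41784910915027457,
      0.04036797903033992, -0.07872200106262882, -0.014467504896790148, 0.014426282505624435,
      -0.0, 0.0, -0.0, 0.0),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.014426282505624435, 0.014467504896790148, -0.07872200106262882,
      -0.04036797903033992, 0.41784910915027457, 0.7589077294536541, 0.41784910915027457,
      -0.04036797903033992, -0.07872200106262882, 0.014467504896790148, 0.014426282505624435,
      0.0, 0.0, 0.0, 0.0),
    rec_hi = c(
      0.0, -0.0019088317364812906, -0.0019142861290887667, 0.016990639867602342,
      0.01193456527972926, -0.04973290349094079, -0.07726317316720414, 0.09405920349573646,
      0.4207962846098268, -0.8259229974584023, 0.4207962846098268, 0.09405920349573646,
      -0.07726317316720414, -0.04973290349094079, 0.01193456527972926, 0.016990639867602342,
      -0.0019142861290887667, -0.0019088317364812906)
  )
)

#' Names of the supported wavelets
#'
#' @return Character vector of wavelet names usable in [denoise_config()]
#'   and [rank_wavelets()].
#' @export
supported_wavelets <- function() names(.wavelet_banks)
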