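"infant_id","ga_weeks","sex","bw_g","bwsds","pnd_days","first_rop_dx_pna_weeks","max_rop_stage","treated","treatment_pna_weeks","last_exam_pna_weeks","weights_g_by_day","hydrocephalus"
"sim000001",30.9,"boy",1340,-0.87,7,,"none",FALSE,,20,"0:1357;3:1368;6:1416;9:1446;12:1517;15:1562;18:1658;21:1745;24:1779;27:1883;30:1938;33:2030;36:2102;39:2203;42:2253",FALSE
"sim000002",27.4,"boy",1017,0,1,,"none",FALSE,,20,"0:1023;3:1046;6:1070;9:1118;12:1195;15:1249;18:1337;21:1419;24:1517;27:1544;30:1639;33:1717;36:1797;39:1872;42:1966",FALSE
"sim000003",29.6,"boy",1423,0.5,11,,"none",FALSE,,20,"0:1415;3:1435;6:1473;9:1517;12:1584;15:1646;18:1756;21:1814;24:1908;27:1968;30:2067;33:2131;36:2201;39:2271;42:2368",FALSE
"sim000004",29.8,"girl",1714,1.97,2,,"none",FALSE,,20,"0:1712;3:1708;6:1785;9:1831;12:1854;15:1976;18:2016;21:2113;24:2185;27:2262;30:2329;33:2430;36:2494;39:2543;42:2634",FALSE
"sim000005",28.3,"boy",914,-1.2,12,,"none",FALSE,,20,"0:895;3:952;6:987;9:997;12:1088;15:1176;18:1231;21:1305;24:1380;27:1471;30:1516;33:1601;36:1673;39:1769;42:1842",FALSE
"sim000006",29.8,"girl",1375,0.13,4,,"none",FALSE,,20,"0:1344;3:1381;6:1417;9:1484;12:1564;15:1653;18:1702;21:1786;24:1847;27:1901;30:2001;33:2067;36:2162;39:2212;42:2278",FALSE
"sim000007",28,"girl",1163,0.33,14,11.1,"1",FALSE,,20,"0:1144;3:1203;6:1212;9:1272;12:1325;15:1381;18:1512;21:1566;24:1629;27:1722;30:1779;33:1853;36:1913;39:2005;42:2072",FALSE
"sim000008",27.3,"girl",1125,0.67,2,,"none",FALSE,,20,"0:1125;3:1132;6:1169;9:1226;12:1304;15:1355;18:1447;21:1510;24:1596;27:1695;30:1732;33:1802;36:1903;39:1975;42:2041",FALSE
"sim000009",31.3,"boy",1681,0.64,9,,"none",FALSE,,20,"0:1689;3:1686;6:1729;9:1816;12:1865;15:1937;18:2027;21:2078;24:2164;27:2242;30:2284;33:2375;36:2487;39:2545;42:2589",FALSE
"sim000010",25.7,"boy",1141,1.94,14,11.1,"2",FALSE,,20,"0:1097;3:1170;6:1196;9:1240;12:1317;15:1412;18:1461;21:1536;24:1634;27:1680;30:1752;33:1838;36:1885;39:2004;42:2094",FALSE
"sim000011",31.6,"girl",1504,-0.55,13,,"none",FALSE,,20,"0:1498;3:1541;6:1557;9:1616;12:1681;15:1766;18:1843;21:1901;24:1985;27:2043;30:2134;33:2203;36:2284;39:2339;42:2418",FALSE
"sim000012",32.5,"boy",1593,-0.77,0,,"none",FALSE,,20,"0:1604;3:1632;6:1648;9:1692;12:1772;15:1829;18:1897;21:1996;24:2079;27:2157;30:2222;33:2307;36:2370;39:2472;42:2486",FALSE
"sim000013",29.8,"girl",1232,-0.65,1,1.8,"3",TRUE,10.5,20,"0:1232;3:1263;6:1280;9:1344;12:1419;15:1462;18:1541;21:1629;24:1715;27:1783;30:1842;33:1935;36:1994;39:2036;42:2162",FALSE
"sim000014",28.6,"boy",995,-1.03,0,,"none",FALSE,,20,"0:1001;3:1029;6:1063;9:1095;12:1183;15:1230;18:1337;21:1392;24:1464;27:1540;30:1619;33:1689;36:1772;39:1836;42:1924",FALSE
"sim000015",28.2,"boy",1004,-0.68,5,8,"1",FALSE,,20,"0:1024;3:1038;6:1061;9:1108;12:1175;15:1250;18:1323;21:1391;24:1475;27:1535;30:1627;33:1715;36:1794;39:1866;42:1910",FALSE
"sim000016",30.9,"boy",1243,-1.43,3,,"none",FALSE,,20,"0:1271;3:1258;6:1307;9:1335;12:1417;15:1514;18:1566;21:1653;24:1709;27:1792;30:1839;33:1940;36:2011;39:2096;42:2146",FALSE
"sim000017",25.6,"girl",932,0.9,36,9.1,"3",TRUE,13.4,20,"0:928;3:950;6:1000;9:1030;12:1065;15:1186;18:1245;21:1338;24:1410;27:1491;30:1565;33:1624;36:1682;39:1765;42:1861",FALSE
"sim000018",31.1,"girl",1496,-0.24,60,,"none",FALSE,,20,"0:1496;3:1510;6:1532;9:1591;12:1666;15:1751;18:1820;21:1911;24:1969;27:2050;30:2110;33:2179;36:2267;39:2357;42:2454",FALSE
"sim000019",25.8,"boy",985,1,1,5.3,"3",FALSE,,20,"0:975;3:1021;6:1070;9:1088;12:1161;15:1241;18:1325;21:1362;24:1436;27:1532;30:1616;33:1671;36:1750;39:1846;42:1929",FALSE
"sim000020",27.2,"girl",987,-0.03,,,"none",FALSE,,20,"0:994;3:1009;6:1058;9:1099;12:1178;15:1238;18:1287;21:1358;24:1444;27:1576;30:1601;33:1681;36:1758;39:1848;42:1897",FALSE
"sim000021",24.6,"girl",916,1.59,25,8.2,"2",FALSE,,20,"",FALSE
"sim000022",25.6,"girl",928,0.86,12,11.1,"3",FALSE,,20,"0:912;3:955;6:994;9:1027;12:1139;15:1171;18:1233;21:1333;24:1369;27:1468;30:1549;33:1614;36:1718;39:1766;42:1865",FALSE
"sim000023",29.6,"girl",1431,0.54,6,,"none",FALSE,,20,"0:1408;3:1475;6:1460;9:1540;12:1609;15:1666;18:1727;21:1831;24:1902;27:1987;30:2074;33:2109;36:2208;39:2259;42:2370",FALSE
"sim000024",31,"boy",1553,0.17,6,,"none",FALSE,,20,"0:1547;3:1589;6:1624;9:1651;12:1694;15:1790;18:1884;21:1960;24:2041;27:2081;30:2169;33:2256;36:2312;39:2388;42:2480",FALSE
"sim000025",30.5,"girl",1758,1.64,7,,"none",FALSE,,20,"0:1750;3:1784;6:1820;9:1876;12:1919;15:2029;18:2072;21:2147;24:2226;27:2304;30:2376;33:2450;36:2521;39:2638;42:2665",FALSE
"sim000026",27.2,"boy",966,-0.13,0,,"none",FALSE,,20,"0:969;3:986;6:1030;9:1076;12:1160;15:1217;18:1262;21:1373;24:1434;27:1529;30:1586;33:1672;36:1749;39:1794;42:1907",FALSE
"sim000027",29.2,"boy",900,-2,4,6.2,"3",TRUE,9.4,20,"0:908;3:917;6:958;9:989;12:1069;15:1175;18:1232;21:1298;24:1358;27:1459;30:1489;33:1599;36:1668;39:1750;42:1831",FALSE
"sim000028",30.7,"boy",1608,0.72,0,,"none",FALSE,,20,"0:1629;3:1633;6:1680;9:1728;12:1791;15:1854;18:1912;21:1991;24:2055;27:2162;30:2202;33:2327;36:2376;39:2447;42:2541",FALSE
"sim000029",22,"girl",358,0.49,19,8.8,"3",TRUE,10.2,20,"",FALSE
"sim000030",23.8,"girl",310,-1.06,19,12.4,"3",TRUE,14.1,20,"",FALSE
"sim000031",28.2,"boy",1334,1.13,17,8.3,"1",FALSE,,20,"0:1330;3:1379;6:1373;9:1455;12:1527;15:1610;18:1676;21:1744;24:1790;27:1894;30:1969;33:2005;36:2091;39:2170;42:2254",FALSE
"sim000032",27.2,"girl",764,-1.21,,,"none",FALSE,,20,"0:755;3:811;6:821;9:867;12:944;15:1003;18:1066;21:1151;24:1237;27:1303;30:1367;33:1472;36:1521;39:1575;42:1695",FALSE
"sim000033",26.3,"boy",918,0.3,38,13.1,"1",FALSE,,20,"0:932;3:949;6:989;9:1009;12:1108;15:1173;18:1248;21:1321;24:1406;27:1439;30:1537;33:1615;36:1707;39:1791;42:1829",FALSE
"sim000034",33.1,"girl",1836,0.08,13,,"none",FALSE,,20,"0:1848;3:1856;6:1891;9:1945;12:2004;15:2080;18:2155;21:2220;24:2298;27:2391;30:2461;33:2522;36:2596;39:2690;42:2743",FALSE
"sim000035",29.6,"girl",1362,0.2,2,,"none",FALSE,,20,"0:1367;3:1382;6:1426;9:1464;12:1548;15:1607;18:1680;21:1763;24:1829;27:1894;30:1984;33:2048;36:2146;39:2184;42:2290",FALSE
"sim000036",29.6,"boy",1273,-0.31,,,"none",FALSE,,20,"0:1285;3:1286;6:1345;9:1383;12:1478;15:1506;18:1562;21:1694;24:1742;27:1802;30:1894;33:1975;36:2029;39:2131;42:2185",FALSE
"sim000037",24.7,"girl",905,1.42,58,,"none",FALSE,,20,"",FALSE
"sim000038",32.9,"girl",1913,0.68,1,,"none",FALSE,,20,"0:1900;3:1926;6:1967;9:2019;12:2053;15:2146;18:2226;21:2297;24:2354;27:2452;30:2558;33:2591;36:2695;39:2769;42:2838",FALSE
"sim000039",23.8,"boy",321,-1.04,16,10.6,"2",FALSE,,20,"",FALSE
"sim000040",29.4,"girl",1303,0.02,13,,"none",FALSE,,20,"0:1290;3:1309;6:1359;9:1422;12:1478;15:1578;18:1621;21:1685;24:1746;27:1850;30:1906;33:1991;36:2078;39:2132;42:2217",FALSE
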